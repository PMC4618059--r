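---
title: "Spectral-count quantitation of AP-MS pull-downs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-count quantitation of AP-MS pull-downs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmsquant)
```

## The experiment this package models

An affinity-purification mass-spectrometry (AP-MS) pull-down immobilizes a
bait — here the C-terminal tail of a G-protein-coupled receptor ending in a
class-1 PDZ-binding motif — on a resin, incubates it with a cell or tissue
lysate, and identifies the retained prey proteins by LC-MS/MS. Two features
dominate the analysis problem:

* **Background binding.** The resin retains abundant sticky proteins whether
  or not the bait is present, so every pull-down is paired with a
  resin-alone control (`'-'`) and specificity is judged by enrichment of the
  bait sample (`'+'`) over that control.
* **Semi-quantitative counts.** Abundance is proxied by the spectral count
  (SC): the number of accepted peptide-spectrum matches (PSMs) attributed to
  a protein group in one sample. Counts are normalized within each sample
  (nSC = SC / total SC of the sample) before samples are compared.

A second design validates candidate direct binders: membranes from cells
expressing the wild-type receptor (WT) or a mutant lacking the PDZ-binding
motif (here called `dPDZ`) are separated into detergent-insoluble (iM) and
detergent-soluble (sM) fractions. A protein recruited to the receptor's
membrane compartment through the motif should be enriched in iM relative to
sM in WT but not in the deletion mutant; the statistic is the fold
enrichment FE = (iM/sM of WT) / (iM/sM of dPDZ), with FE > 2 read as
evidence of direct, motif-dependent association.

## Peptide acceptance

PSMs arrive as a flat TSV (one row per identified spectrum, all engine
scores on the row; an absent score means that engine did not identify the
spectrum). `filter_criteria()` encodes the acceptance rules:

| knob | default | meaning |
|---|---|---|
| `mascot_min` | 40 | Mascot ion score, strict `>` |
| `deltacn_min` | 0.10 | Sequest deltaCn, strict `>` (required with XCorr) |
| `xcorr_min_by_charge` | 1.5 / 2.0 / 2.2 / 2.5 | Sequest XCorr by precursor charge 1+..4+; higher charges use the 4+ value |
| `xtandem_min_neg_log_e` | 2.0 | X!Tandem −log10(Expect), strict `>` |
| `peptide_probability_min` | 0.95 | PeptideProphet-style probability, `>=`, applied only when present |
| `engine_combination` | `any_engine` | one passing engine suffices; `all_present_engines` is a stricter mode |

All engine thresholds are *strict* inequalities, following the "greater
than" wording of the protocol they encode. Two deviations from that
protocol's literal text are deliberate and are echoed in the `run_all()`
log whenever defaults are used:

* The protocol text states a probability cut-off of "greater than 0.1%",
  which would accept nearly everything; we treat it as a misprint and
  expose the threshold as a knob defaulting to 0.95.
* The probability filter and the engine thresholds are applied
  *conjunctively* (probability, when present, AND engine support). The
  alternative reading — probability as an alternative route to acceptance —
  is available by setting `peptide_probability_min = 0`.

## Protein inference

`build_peptide_map()` maps accepted peptides to accessions, either trusting
the PSM accession lists or re-deriving them by exact substring search of
the FASTA database with I/L treated as equivalent (isobaric residues are
indistinguishable by MS/MS). `group_by_parsimony()` then:

1. merges proteins with identical accepted-peptide sets into one group
   (indistinguishable by the evidence);
2. absorbs any protein whose peptide set is a strict subset of another's
   into the subsuming group, recording it in `subsumed_members`;
3. assigns peptides still shared between distinct surviving groups by the
   razor rule — to the group with more distinct peptides, ties broken by
   the lexicographically smallest representative.

The razor rule guarantees **spectral-count conservation**: every accepted
PSM is counted exactly once, so group SCs sum to the accepted PSM count.
This matters downstream because nSC normalization and the fraction double
ratios implicitly assume counts are not duplicated across groups.

Subsumption-based parsimony can keep more groups than a minimum set cover
on cyclic sharing structures (e.g. three proteins pairwise sharing one
peptide each admit a two-protein cover but contain no subset pair). We keep
all three in that situation: collapsing them would require an arbitrary
choice of which protein to discard without any subset evidence, and the
published grouping semantics ("proteins that contained similar peptides and
could not be differentiated were grouped") is subset/identity-based, not
cover-minimal. The test suite checks the implementation against an
independent brute-force re-evaluation of these rules on all small random
instances it generates.

`accept_proteins()` keeps groups with at least 2 distinct peptides and
protein probability ≥ 0.99. Probabilities from an upstream
ProteinProphet-style model are not recomputed; instead the independence
combination `1 − Π(1 − p_i)` over the group's best per-peptide
probabilities stands in (peptides without a probability contribute the
peptide-filter threshold, 0.95). Any monotone combiner preserves the
acceptance semantics; the threshold and stand-in are knobs. The acceptance
comparison carries a `1e-9` tolerance so boundary cases (two 0.9 peptides
giving exactly 0.99) are not lost to floating-point representation.

## Quantitation and hit calling

`compute_nsc()` normalizes within one sample's elution: nSC = SC / Σ SC
over all accepted groups of that sample, so Σ nSC = 1. `call_enrichment()`
joins the `'+'` and `'-'` quantitations over the union of groups and
computes the ratio nSC+ / nSC−, with `+Inf` for bait-exclusive groups. The
default hit rule is:

* **significant**: raw SC in `'+'` strictly greater than `sc_min`
  (default 10; `resolve_sc_min()` supports per-sample overrides such as the
  stricter `> 20` used for one lysate in the original screen to shrink its
  hit list); and
* **exclusive**: SC in `'-'` equal to zero.

Exclusivity is the default because in the screen this package models, hits
were essentially absent from the controls; `ratio_min` enables a tolerant
mode that also accepts finite ratios. Significance is applied to raw SC of
the bait sample, not nSC — a parenthetical "(nSC > 10 to ∞)" in the source
text conflates the two (nSC cannot exceed 1), which the run log notes.

`annotate_hits()` partitions hits into PDZ / non-PDZ against the packaged
reference (26 PDZ proteins of the original pull-down screen plus the PDZ
proteins seen only in the validation experiment; extensible via any TSV of
the same shape). Matching is case-insensitive by primary name first, then
synonyms — a name reused as another protein's synonym always matches
itself. `intersect_hitsets()` computes the full Venn decomposition across
samples; the all-samples cell is the conserved interactor fingerprint.

## Fraction validation

`fraction_ratio()` classifies each protein within one construct:
`only_iM` (SC > `sc_min` in iM, 0 in sM), `only_sM` (symmetric),
`not_significant` (SC < `sc_min` in both), otherwise a numeric
nSC_iM / nSC_sM ratio. One boundary cell is not covered by these published
classes — one fraction exactly at `sc_min`, the other 0, leaving the ratio
denominator empty; we classify it `not_significant` as the conservative
tie-break (it was not significant under the strict `>` rule).

`fold_enrichment()` merges the two constructs' ratio maps; FE is defined
only where both sides carry numeric ratios, and displayed rounded
**half-up** to one decimal (`round_half_up()`), which reproduces the
published display column for all six numeric rows of the validation table:

```{r table3}
tab <- membrane_fraction_table()
fe <- fold_enrichment(tab$wt, tab$dpdz)
fe[, c("name", "ratio_wt", "ratio_dpdz", "fold_enrichment", "display_fe")]
classify_direct_binders(fe, fe_min = 2.0)
```

`classify_direct_binders()` applies a strict FE > 2 call; records with a
status class on either side are never called (internal-control proteins
that are `only_iM` in both constructs stay uncalled, as they should).

## The synthetic-data generator

`simulate_pulldown()` and `simulate_fractionation()` generate PSM tables
with ground truth in sidecar files (never in the PSM tables themselves, so
the pipeline cannot see it). The model:

* **Counts.** Per protein per sample, PSM counts are Poisson with
  log-normal protein-level rates — the minimal overdispersed
  spectral-count model. The background abundance log-normal has mean 4
  and `sdlog` 0.7 by default: most background binders sit at SC 1–10 with
  a tail above the significance cut-off that is present in *both* samples
  and therefore never exclusive.
* **Specific binding.** A true interactor's control-sample rate is the
  residual carry-over `-log(exclusive_minus_prob)` (default 0.95, i.e. a
  control SC of zero with probability 0.95 — the calibration that makes
  the exclusivity hit rule meaningful). Its bait-sample rate adds
  `(enrichment_factor − 1) ×` abundance on top, so `enrichment_factor = 1`
  collapses the generator to the null in which recall equals the
  false-positive rate. This additive form is deliberate: tying the control
  rate multiplicatively to abundance cannot simultaneously give
  near-certain control absence and bait counts above the significance
  cut-off at any modest enrichment factor.
* **Sequences.** Proteins are concatenations of unique random tryptic
  peptides (7–25 residues, ending K/R, never followed by P), so in-silico
  digestion (`digest_tryptic()`) recovers exactly the generating peptides.
  Missed cleavages are not modeled by default.
* **Scores.** Engine scores come from overlapping correct/incorrect
  normal distributions (e.g. Mascot: N(60, 15) versus N(25, 10), truncated
  at 0); probabilities from Beta(40, 1) versus Beta(1, 10). A configurable
  fraction of PSMs (default 5%) are incorrect: decoy peptides with
  misassigned accessions and scores from the incorrect distributions —
  they are what the score thresholds are for.
* **Fractionation.** A panel of PDZ proteins is quantified at a base rate
  of 150 counts; designated binders get rate × FE-target in WT-iM only. A
  ballast background protein absorbs the rate differences so every sample
  has the same expected total count, which keeps nSC normalization from
  biasing the double ratio; in the zero-variance debug mode (counts equal
  rounded expectations, deterministic peptide assignment) the recovered FE
  equals the target exactly.

What the generator does **not** emulate: peptide sharing between homologous
proteins (generated peptides are unique, so parsimony stress comes from the
dedicated small-instance tests, not the end-to-end runs), spectrum-level
properties (m/z, intensity, retention time), protein length effects on
count rates (no NSAF-style normalization is implemented), and replicate
structure (the modeled screen is single-run). Passing end-to-end recovery
therefore demonstrates the counting, grouping and calling logic under the
modeled statistical structure — not robustness to every failure mode of
real lysate data.

## Determinism and problem sizes

Every simulator entry point seeds R's RNG explicitly (Mersenne-Twister,
inversion, rejection sampling) with the configured seed plus a fixed
per-stage offset, so one seed gives byte-identical output files. The test
suite and the acceptance script run the end-to-end recovery at the default
design size — 925 proteins (900 background + 25 interactors) — over 10
pull-down seeds and 20 fractionation seeds, which completes in a few
minutes on one CPU while holding the Monte-Carlo error of the recovered
mean FE near 0.05.

## Known limitations

* Protein probabilities are an independence approximation, not a
  ProteinProphet reimplementation; with correlated peptide evidence the
  combined probability is optimistic.
* No decoy-based FDR estimation; the score thresholds are taken as given.
* Spectral counts shared between surviving groups are razor-assigned, so
  per-group SCs can differ from tools that count shared spectra once per
  protein (which inflates totals); totals here always sum to the accepted
  PSM count.
* The supplementary-table count checks require user-supplied TSV exports
  of the deposited spreadsheets; they are not redistributable with the
  package.
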