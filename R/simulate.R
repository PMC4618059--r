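#' Configuration for the synthetic PSM generator
#'
#' Defines the study conditions emulated by the generator: a two-condition
#' pull-down (bait-bound resin `'+'` versus resin-alone `'-'`) and a
#' two-fraction by two-construct membrane validation experiment. Counts are
#' Poisson with log-normal protein-level rates (the standard overdispersed
#' spectral-count model); engine scores are drawn from overlapping
#' correct/incorrect distributions.
#'
#' Specific binding is modeled additively: a true interactor's control rate
#' is the small residual carry-over `-log(exclusive_minus_prob)` (so it is
#' absent from the control with probability `exclusive_minus_prob`), and its
#' bait-sample rate adds `(enrichment_factor - 1)` times its abundance on
#' top. `enrichment_factor = 1` therefore collapses the design to the null in
#' which true interactors are indistinguishable from their own control
#' behavior.
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_background Number of background (non-specific) proteins.
#' @param n_true_interactors Number of bait-specific interactors.
#' @param pdz_fraction Fraction of true interactors given PDZ reference
#'   names (and hence PDZ annotation).
#' @param enrichment_factor Multiplier of a true interactor's abundance
#'   contributing to its `'+'`-sample rate.
#' @param background_abundance Mean of the log-normal over per-protein
#'   Poisson rates.
#' @param abundance_sdlog Log-scale SD of the abundance log-normal.
#' @param exclusive_minus_prob Probability that a true interactor has zero
#'   control-sample spectra.
#' @param tryptic_peptide_length Length range of generated tryptic peptides.
#' @param peptides_per_protein Range of peptides per generated protein.
#' @param charge_mix Probability vector over precursor charges 1-4.
#' @param incorrect_psm_rate Fraction of PSMs that are incorrect (decoy
#'   peptide, misassigned accession).
#' @param engine_presence_prob Probability each engine scored a spectrum
#'   (at least one is always present).
#' @param probability_present_prob Probability a PSM carries a peptide
#'   probability.
#' @param score_model Per-engine parameters of the correct and incorrect
#'   score distributions.
#' @param validation_panel PDZ proteins quantified in the fractionation
#'   design.
#' @param validation_binders Panel members given motif-dependent iM
#'   enrichment in the WT construct.
#' @param validation_fe Target fold enrichment of the binders.
#' @param validation_abundance Base Poisson rate of panel proteins.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_background = 900L,
                             n_true_interactors = 25L,
                             pdz_fraction = 0.6,
                             enrichment_factor = 20,
                             background_abundance = 4,
                             abundance_sdlog = 0.7,
                             exclusive_minus_prob = 0.95,
                             tryptic_peptide_length = c(7L, 25L),
                             peptides_per_protein = c(12L, 30L),
                             charge_mix = c(`1` = 0.05, `2` = 0.60,
                                            `3` = 0.25, `4` = 0.10),
                             incorrect_psm_rate = 0.05,
                             engine_presence_prob = 0.9,
                             probability_present_prob = 0.95,
                             score_model = default_score_model(),
                             validation_panel = c("DLG1", "TJP2", "CSKP",
                                                  "SCRIB", "TJP1", "NEB2",
                                                  "NEB1", "MPP5", "PDZD8",
                                                  "AFAD"),
                             validation_binders = c("DLG1", "TJP2"),
                             validation_fe = 2.2,
                             validation_abundance = 150) {
  stopifnot(
    length(seed) == 1, is.finite(seed),
    n_background >= 1, n_true_interactors >= 1,
    pdz_fraction >= 0, pdz_fraction <= 1,
    enrichment_factor > 0, background_abundance > 0, abundance_sdlog > 0,
    exclusive_minus_prob > 0, exclusive_minus_prob < 1,
    incorrect_psm_rate >= 0, incorrect_psm_rate <= 1,
    abs(sum(charge_mix) - 1) < 1e-8, all(charge_mix >= 0),
    validation_fe > 0, validation_abundance > 0,
    all(validation_binders %in% validation_panel)
  )
  structure(
    list(seed = as.integer(seed),
         n_background = as.integer(n_background),
         n_true_interactors = as.integer(n_true_interactors),
         pdz_fraction = pdz_fraction,
         enrichment_factor = enrichment_factor,
         background_abundance = background_abundance,
         abundance_sdlog = abundance_sdlog,
         exclusive_minus_prob = exclusive_minus_prob,
         tryptic_peptide_length = as.integer(tryptic_peptide_length),
         peptides_per_protein = as.integer(peptides_per_protein),
         charge_mix = charge_mix,
         incorrect_psm_rate = incorrect_psm_rate,
         engine_presence_prob = engine_presence_prob,
         probability_present_prob = probability_present_prob,
         score_model = score_model,
         validation_panel = validation_panel,
         validation_binders = validation_binders,
         validation_fe = validation_fe,
         validation_abundance = validation_abundance),
    class = "synthetic_config"
  )
}

#' Default engine score model
#'
#' Normal score distributions for correct and incorrect PSMs per engine
#' (truncated at zero where the score is nonnegative), a clamped deltaCn
#' model, and beta-distributed peptide probabilities. The correct and
#' incorrect distributions overlap, so thresholding trades sensitivity
#' against contamination as in real search results.
#'
#' @return A named list of parameter vectors.
#' @export
default_score_model <- function() {
  list(
    mascot  = c(correct_mean = 60, correct_sd = 15,
                incorrect_mean = 25, incorrect_sd = 10),
    xcorr   = c(correct_mean = 3.2, correct_sd = 0.6,
                incorrect_mean = 1.3, incorrect_sd = 0.4),
    deltacn = c(correct_mean = 0.25, correct_sd = 0.08,
                incorrect_mean = 0.05, incorrect_sd = 0.03),
    xtandem = c(correct_mean = 4.0, correct_sd = 1.5,
                incorrect_mean = 0.8, incorrect_sd = 0.8),
    probability = c(correct_shape1 = 40, correct_shape2 = 1,
                    incorrect_shape1 = 1, incorrect_shape2 = 10)
  )
}

.set_sim_seed <- function(seed, offset = 0L) {
  s <- (as.numeric(seed) + offset) %% (.Machine$integer.max - 1)
  set.seed(as.integer(s), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

.aa_interior <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        c("K", "R", "P"))

.random_peptide <- function(len) {
  body <- sample(.aa_interior, len - 1L, replace = TRUE)
  # first residue must not be proline (already excluded) and the peptide
  # ends at a tryptic site
  paste0(paste(body, collapse = ""), sample(c("K", "R"), 1L))
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is proline and returns
#' the unique peptides within the given length range.
#'
#' @param sequence Amino-acid string.
#' @param length_range Two-element integer vector (min, max).
#' @return Character vector of peptides.
#' @export
digest_tryptic <- function(sequence, length_range = c(7L, 25L)) {
  residues <- strsplit(sequence, "")[[1]]
  n <- length(residues)
  cut_after <- which(residues %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n &
                           residues[pmin(cut_after + 1L, n)] != "P" |
                           cut_after == n]
  bounds <- unique(c(0L, cut_after, n))
  starts <- utils::head(bounds, -1) + 1L
  ends <- bounds[-1]
  peps <- substring(sequence, starts, ends)
  peps <- peps[nchar(peps) >= length_range[1] &
                 nchar(peps) <= length_range[2]]
  unique(peps)
}

#' Simulate a proteome with ground-truth labels
#'
#' Generates random protein sequences as concatenations of unique tryptic
#' peptides (cleave after K/R, never before P), assigns roles (bait-specific
#' true interactor versus background binder), gives a configurable fraction
#' of the true interactors names from the packaged PDZ reference (so the
#' annotation stage recognizes them), and draws each protein's abundance
#' from the log-normal rate model.
#'
#' @param config A [synthetic_config()].
#' @return A list with `db` (protein database tibble), `peptides` (named
#'   list accession -> tryptic peptides), `truth` (tibble with `accession`,
#'   `role`, `is_pdz`, `abundance`), and `config`.
#' @export
simulate_proteome <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  .set_sim_seed(config$seed, 0L)

  n_true <- config$n_true_interactors
  n_pdz <- min(round(config$pdz_fraction * n_true), n_true)
  ref_names <- pdz_reference()$name
  pdz_pool <- unique(c(config$validation_panel, ref_names))
  pdz_pool <- pdz_pool[pdz_pool %in% ref_names]
  if (n_pdz > length(pdz_pool)) n_pdz <- length(pdz_pool)
  names_true <- c(pdz_pool[seq_len(n_pdz)],
                  sprintf("INT%02d", seq_len(n_true - n_pdz)))
  names_bg <- sprintf("BG%04d", seq_len(config$n_background))
  accession <- c(names_true, names_bg)
  role <- c(rep("true_interactor", n_true),
            rep("background", config$n_background))
  is_pdz <- accession %in% ref_names & role == "true_interactor"

  lens <- config$tryptic_peptide_length
  nper <- config$peptides_per_protein
  peptides <- vector("list", length(accession))
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(accession)) {
    k <- sample(seq(nper[1], nper[2]), 1L)
    peps <- character(0)
    while (length(peps) < k) {
      p <- .random_peptide(sample(seq(lens[1], lens[2]), 1L))
      if (is.null(seen[[p]])) {
        assign(p, TRUE, envir = seen)
        peps <- c(peps, p)
      }
    }
    peptides[[i]] <- peps
  }
  names(peptides) <- accession

  mu <- log(config$background_abundance) - config$abundance_sdlog^2 / 2
  abundance <- stats::rlnorm(length(accession), meanlog = mu,
                             sdlog = config$abundance_sdlog)

  db <- tibble::tibble(
    accession = accession,
    description = ifelse(role == "true_interactor",
                         "synthetic bait-specific interactor",
                         "synthetic background binder"),
    sequence = vapply(peptides, paste, character(1), collapse = "")
  )
  truth <- tibble::tibble(accession = accession, role = role,
                          is_pdz = is_pdz, abundance = abundance)
  list(db = db, peptides = peptides, truth = truth, config = config)
}

# Draw engine scores and assemble PSM rows for one sample. Uses the current
# RNG stream; deterministic given the caller's seeding.
.generate_sample_psms <- function(sample_id, condition, construct, rates,
                                  proteome, config, zero_variance = FALSE) {
  counts <- if (zero_variance) {
    as.integer(round(rates))
  } else {
    stats::rpois(length(rates), rates)
  }
  names(counts) <- names(rates)
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0) {
    stop("simulated sample ", sample_id, " has no spectra; raise abundances",
         call. = FALSE)
  }
  source_acc <- rep(names(counts), counts)
  correct <- if (zero_variance || config$incorrect_psm_rate == 0) {
    rep(TRUE, n)
  } else {
    stats::runif(n) >= config$incorrect_psm_rate
  }

  peptide <- character(n)
  accession <- source_acc
  for (acc in names(counts)) {
    idx <- which(source_acc == acc)
    pool <- proteome$peptides[[acc]]
    peptide[idx] <- if (zero_variance) {
      # deterministic round-robin so identical counts give identical
      # peptide inventories in every sample
      pool[((seq_along(idx) - 1L) %% length(pool)) + 1L]
    } else {
      pool[sample.int(length(pool), length(idx), replace = TRUE)]
    }
  }
  n_bad <- sum(!correct)
  if (n_bad > 0) {
    lens <- config$tryptic_peptide_length
    peptide[!correct] <- vapply(
      sample(seq(lens[1], lens[2]), n_bad, replace = TRUE),
      .random_peptide, character(1)
    )
    accession[!correct] <- sample(proteome$db$accession, n_bad,
                                  replace = TRUE)
  }

  charge <- as.integer(sample(names(config$charge_mix), n, replace = TRUE,
                              prob = config$charge_mix))
  m <- config$score_model
  draw <- function(par, ok) {
    mean_ <- ifelse(ok, par[["correct_mean"]], par[["incorrect_mean"]])
    sd_ <- ifelse(ok, par[["correct_sd"]], par[["incorrect_sd"]])
    if (zero_variance) mean_ else stats::rnorm(n, mean_, sd_)
  }
  mascot <- pmax(0, draw(m$mascot, correct))
  xcorr <- pmax(0.01, draw(m$xcorr, correct))
  deltacn <- pmin(1, pmax(0, draw(m$deltacn, correct)))
  xtandem <- draw(m$xtandem, correct)
  pb <- m$probability
  probability <- if (zero_variance) {
    rep(0.99, n)
  } else {
    ifelse(correct,
           stats::rbeta(n, pb[["correct_shape1"]], pb[["correct_shape2"]]),
           stats::rbeta(n, pb[["incorrect_shape1"]],
                        pb[["incorrect_shape2"]]))
  }

  present <- if (zero_variance) {
    matrix(TRUE, n, 3)
  } else {
    matrix(stats::runif(3 * n) < config$engine_presence_prob, n, 3)
  }
  none <- rowSums(present) == 0
  present[none, 1] <- TRUE
  prob_present <- if (zero_variance) rep(TRUE, n) else {
    stats::runif(n) < config$probability_present_prob
  }

  mascot[!present[, 1]] <- NA_real_
  xcorr[!present[, 2]] <- NA_real_
  deltacn[!present[, 2]] <- NA_real_
  xtandem[!present[, 3]] <- NA_real_
  probability[!prob_present] <- NA_real_

  psms <- tibble::tibble(
    sample_id = sample_id,
    condition = condition,
    construct = construct,
    spectrum_id = sprintf("sp%06d", seq_len(n)),
    peptide = peptide,
    charge = charge,
    accessions = accession,
    mascot_ion_score = mascot,
    sequest_xcorr = xcorr,
    sequest_deltacn = deltacn,
    xtandem_neg_log_e = xtandem,
    peptide_probability = probability,
    mod_string = NA_character_
  )
  truth <- tibble::tibble(
    sample_id = sample_id,
    spectrum_id = psms$spectrum_id,
    source_accession = ifelse(correct, source_acc, NA_character_),
    correct = correct
  )
  list(psms = psms, truth = truth)
}

#' Simulate a bait-versus-control pull-down
#'
#' Generates the PSM tables of a `'+'` (bait-bound resin) and `'-'`
#' (resin-alone) sample pair. Background binders share one Poisson rate in
#' both samples; true interactors have the residual carry-over rate in the
#' control and an `enrichment_factor`-scaled rate in the bait sample (see
#' [synthetic_config()]). Ground truth never enters the PSM tables; it is
#' returned (and written) as sidecar tables.
#'
#' @param config A [synthetic_config()].
#' @param proteome Optional output of [simulate_proteome()]; simulated from
#'   `config` when omitted.
#' @param outdir Optional directory; when given, writes `psm_plus.tsv`,
#'   `psm_minus.tsv`, `proteome.fasta`, `truth_proteins.tsv`,
#'   `truth_psms.tsv`.
#' @return A list with `plus` and `minus` PSM tibbles, `truth_proteins`
#'   (per-protein roles and rates), `truth_psms` (per-spectrum truth),
#'   and `proteome`.
#' @export
simulate_pulldown <- function(config = synthetic_config(), proteome = NULL,
                              outdir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(proteome)) proteome <- simulate_proteome(config)
  .set_sim_seed(config$seed, 1L)

  truth <- proteome$truth
  carryover <- -log(config$exclusive_minus_prob)
  is_true <- truth$role == "true_interactor"
  rate_minus <- ifelse(is_true, carryover, truth$abundance)
  rate_plus <- ifelse(is_true,
                      carryover +
                        (config$enrichment_factor - 1) * truth$abundance,
                      truth$abundance)
  names(rate_plus) <- names(rate_minus) <- truth$accession

  plus <- .generate_sample_psms("pulldown_plus", "plus", "none", rate_plus,
                                proteome, config)
  minus <- .generate_sample_psms("pulldown_minus", "minus", "none",
                                 rate_minus, proteome, config)

  truth_proteins <- tibble::tibble(
    accession = truth$accession, role = truth$role, is_pdz = truth$is_pdz,
    rate_plus = unname(rate_plus), rate_minus = unname(rate_minus)
  )
  out <- list(plus = plus$psms, minus = minus$psms,
              truth_proteins = truth_proteins,
              truth_psms = dplyr::bind_rows(plus$truth, minus$truth),
              proteome = proteome)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_psm_table(out$plus, file.path(outdir, "psm_plus.tsv"))
    write_psm_table(out$minus, file.path(outdir, "psm_minus.tsv"))
    write_fasta(proteome$db, file.path(outdir, "proteome.fasta"))
    write_report(out$truth_proteins, file.path(outdir, "truth_proteins.tsv"))
    write_report(out$truth_psms, file.path(outdir, "truth_psms.tsv"))
  }
  out
}

#' Simulate the two-fraction, two-construct validation experiment
#'
#' Generates four PSM tables (WT-iM, WT-sM, dPDZ-iM, dPDZ-sM). A designated
#' panel of PDZ proteins is quantified at high abundance; panel members named
#' in `validation_binders` receive motif-dependent iM enrichment in the WT
#' construct only, with expected fold enrichment equal to `validation_fe`;
#' all other proteins have equal expected rates across fractions and
#' constructs (fold enrichment 1). A ballast background protein absorbs the
#' rate differences so that every sample has the same expected total count,
#' which keeps nSC normalization from biasing the double ratio.
#'
#' @param config A [synthetic_config()].
#' @param proteome Optional [simulate_proteome()] output.
#' @param outdir Optional directory for the four PSM TSVs plus sidecars.
#' @param zero_variance Debug mode: counts equal rounded expectations and
#'   all scores are at their correct means, so downstream fold enrichment is
#'   exact.
#' @return A list with `samples` (named list of four PSM tibbles),
#'   `truth_proteins` (per-protein per-sample rates, panel/binder flags,
#'   `target_fe`), `truth_psms`, and `proteome`.
#' @export
simulate_fractionation <- function(config = synthetic_config(),
                                   proteome = NULL, outdir = NULL,
                                   zero_variance = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(proteome)) proteome <- simulate_proteome(config)
  .set_sim_seed(config$seed, 2L)

  truth <- proteome$truth
  acc <- truth$accession
  panel <- intersect(config$validation_panel, acc)
  binders <- intersect(config$validation_binders, panel)
  base <- stats::setNames(truth$abundance, acc)
  base[panel] <- config$validation_abundance

  rates <- list(
    wt_iM = base, wt_sM = base, dpdz_iM = base, dpdz_sM = base
  )
  rates$wt_iM[binders] <- config$validation_abundance * config$validation_fe
  # ballast protein equalizes expected totals across the four samples
  totals <- vapply(rates, sum, numeric(1))
  ballast <- max(totals) - totals + 50
  for (s in names(rates)) {
    rates[[s]] <- c(rates[[s]], BGBALLAST = unname(ballast[s]))
  }
  proteome_b <- proteome
  proteome_b$peptides$BGBALLAST <- local({
    k <- 20L
    lens <- config$tryptic_peptide_length
    vapply(sample(seq(lens[1], lens[2]), k, replace = TRUE),
           .random_peptide, character(1))
  })
  proteome_b$db <- dplyr::bind_rows(
    proteome$db,
    tibble::tibble(accession = "BGBALLAST",
                   description = "synthetic total-count ballast",
                   sequence = paste(proteome_b$peptides$BGBALLAST,
                                    collapse = ""))
  )

  meta <- list(
    wt_iM = c("iM", "WT"), wt_sM = c("sM", "WT"),
    dpdz_iM = c("iM", "dPDZ"), dpdz_sM = c("sM", "dPDZ")
  )
  samples <- list()
  truth_psms <- list()
  for (s in names(rates)) {
    g <- .generate_sample_psms(s, meta[[s]][1], meta[[s]][2], rates[[s]],
                               proteome_b, config, zero_variance)
    samples[[s]] <- g$psms
    truth_psms[[s]] <- g$truth
  }

  acc_all <- c(acc, "BGBALLAST")
  truth_proteins <- tibble::tibble(
    accession = acc_all,
    in_panel = acc_all %in% panel,
    is_binder = acc_all %in% binders,
    target_fe = ifelse(acc_all %in% binders, config$validation_fe,
                       ifelse(acc_all == "BGBALLAST", NA_real_, 1)),
    rate_wt_iM = unname(rates$wt_iM[acc_all]),
    rate_wt_sM = unname(rates$wt_sM[acc_all]),
    rate_dpdz_iM = unname(rates$dpdz_iM[acc_all]),
    rate_dpdz_sM = unname(rates$dpdz_sM[acc_all])
  )
  out <- list(samples = samples, truth_proteins = truth_proteins,
              truth_psms = dplyr::bind_rows(truth_psms),
              proteome = proteome_b)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (s in names(samples)) {
      write_psm_table(samples[[s]], file.path(outdir,
                                              paste0("psm_", s, ".tsv")))
    }
    write_fasta(proteome_b$db, file.path(outdir, "proteome.fasta"))
    write_report(truth_proteins, file.path(outdir, "truth_proteins.tsv"))
    write_report(out$truth_psms, file.path(outdir, "truth_psms.tsv"))
  }
  out
}
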