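# Shared fixtures and independent oracles for the test suite.

# Build PSM rows with sensible defaults; any field can be overridden.
make_psm <- function(n = 1, sample_id = "s1", condition = "plus",
                     construct = "none",
                     spectrum_id = sprintf("sp%03d", seq_len(n)),
                     peptide = "ELVISLK", charge = 2L,
                     accessions = "P1",
                     mascot_ion_score = 60, sequest_xcorr = NA_real_,
                     sequest_deltacn = NA_real_,
                     xtandem_neg_log_e = NA_real_,
                     peptide_probability = NA_real_,
                     mod_string = NA_character_) {
  tibble::tibble(
    sample_id = sample_id, condition = condition, construct = construct,
    spectrum_id = spectrum_id, peptide = peptide, charge = charge,
    accessions = accessions, mascot_ion_score = mascot_ion_score,
    sequest_xcorr = sequest_xcorr, sequest_deltacn = sequest_deltacn,
    xtandem_neg_log_e = xtandem_neg_log_e,
    peptide_probability = peptide_probability, mod_string = mod_string
  )
}

# Random PSM tables spanning present/absent scores around the thresholds.
random_psms <- function(n, seed) {
  set.seed(seed)
  maybe <- function(x, p = 0.3) ifelse(runif(n) < p, NA_real_, x)
  psms <- make_psm(
    n = n,
    spectrum_id = sprintf("r%04d", seq_len(n)),
    peptide = replicate(n, paste(sample(LETTERS[c(1, 3:9, 11:14, 16:20)],
                                        8, replace = TRUE), collapse = "")),
    charge = sample(1:6, n, replace = TRUE),
    mascot_ion_score = maybe(runif(n, 0, 80)),
    sequest_xcorr = maybe(runif(n, 0, 4)),
    sequest_deltacn = maybe(runif(n, 0, 0.5)),
    xtandem_neg_log_e = maybe(runif(n, -1, 5)),
    peptide_probability = maybe(runif(n), 0.5)
  )
  psms
}

# Independent brute-force re-evaluation of the published acceptance rules,
# written record-by-record straight from their wording.
oracle_filter <- function(psms, criteria) {
  sapply(seq_len(nrow(psms)), function(i) {
    r <- as.list(psms[i, ])
    mascot <- !is.na(r$mascot_ion_score) &&
      r$mascot_ion_score > criteria$mascot_min
    xthr <- if (r$charge >= 4) criteria$xcorr_min_by_charge[["4"]] else {
      criteria$xcorr_min_by_charge[[as.character(r$charge)]]
    }
    sequest <- !is.na(r$sequest_xcorr) && !is.na(r$sequest_deltacn) &&
      r$sequest_deltacn > criteria$deltacn_min && r$sequest_xcorr > xthr
    xtandem <- !is.na(r$xtandem_neg_log_e) &&
      r$xtandem_neg_log_e > criteria$xtandem_min_neg_log_e
    engine <- if (criteria$engine_combination == "any_engine") {
      mascot || sequest || xtandem
    } else {
      present <- c(!is.na(r$mascot_ion_score), !is.na(r$sequest_xcorr),
                   !is.na(r$xtandem_neg_log_e))
      any(present) && all(c(mascot, sequest, xtandem)[present])
    }
    prob <- is.na(r$peptide_probability) ||
      r$peptide_probability >= criteria$peptide_probability_min
    prob && engine
  })
}

# Independent brute-force grouping from the parsimony definition: merge
# identical peptide sets, absorb strict subsets (into the largest superset,
# ties by smallest representative), razor-assign shared peptides. Works on a
# peptide -> accessions map; returns surviving groups as a named list
# representative -> list(members, peptides, razor_peptides).
oracle_parsimony <- function(map) {
  prots <- sort(unique(unlist(map)))
  pepsets <- lapply(prots, function(a) {
    sort(names(map)[vapply(map, function(x) a %in% x, logical(1))])
  })
  names(pepsets) <- prots
  keys <- vapply(pepsets, paste, character(1), collapse = "|")
  groups <- lapply(split(prots, keys), sort)
  reps <- vapply(groups, `[`, character(1), 1)
  names(groups) <- reps
  sets <- lapply(reps, function(r) pepsets[[r]])
  names(sets) <- reps
  # strict-subset absorption via exhaustive pairwise comparison
  absorbed <- rep(FALSE, length(reps))
  names(absorbed) <- reps
  for (a in reps) {
    supersets <- reps[vapply(reps, function(b) {
      length(sets[[b]]) > length(sets[[a]]) && all(sets[[a]] %in% sets[[b]])
    }, logical(1))]
    if (length(supersets) > 0) absorbed[a] <- TRUE
  }
  surv <- reps[!absorbed]
  razor <- lapply(surv, function(r) character(0))
  names(razor) <- surv
  for (p in names(map)) {
    owners <- surv[vapply(surv, function(r) p %in% sets[[r]], logical(1))]
    if (length(owners) == 0) next
    sizes <- vapply(owners, function(r) length(sets[[r]]), integer(1))
    win <- owners[order(-sizes, owners)][1]
    razor[[win]] <- c(razor[[win]], p)
  }
  lapply(surv, function(r) {
    list(members = groups[[r]], peptides = sets[[r]],
         razor_peptides = sort(razor[[r]]))
  }) |> stats::setNames(surv)
}

# Random small peptide-protein instances for the parsimony properties.
random_instance <- function(seed, max_prot = 8, max_pep = 12) {
  set.seed(seed)
  n_prot <- sample(2:max_prot, 1)
  n_pep <- sample(3:max_pep, 1)
  prots <- sprintf("P%02d", seq_len(n_prot))
  peps <- sprintf("PEPTIDE%02dK", seq_len(n_pep))
  map <- lapply(peps, function(p) {
    sort(sample(prots, sample(1:min(3, n_prot), 1)))
  })
  names(map) <- peps
  map
}

# PSMs realizing a peptide map: one PSM per peptide occurrence count.
psms_for_map <- function(map, counts = NULL) {
  peps <- names(map)
  if (is.null(counts)) counts <- rep(1L, length(peps))
  rows <- rep(seq_along(peps), counts)
  make_psm(
    n = length(rows),
    spectrum_id = sprintf("m%04d", seq_along(rows)),
    peptide = peps[rows],
    accessions = vapply(map[rows], paste, character(1), collapse = ";")
  )
}

# Minimal sample_quant for quantitation tests.
quant_of <- function(sc, sample_id = "q", condition = "plus") {
  groups <- tibble::tibble(
    representative = names(sc),
    spectral_count = as.integer(sc)
  )
  compute_nsc(groups, sample_id = sample_id, condition = condition)
}
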