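#' Map accepted peptides to protein accessions
#'
#' Builds the peptide-to-protein map used by parsimony grouping. By default
#' the accession lists carried on the PSMs are taken at face value; with
#' `remap = TRUE` each peptide's accession set is recomputed by exact
#' substring search against the protein database, treating isoleucine and
#' leucine as equivalent (isobaric residues cannot be distinguished by
#' MS/MS). A remapped peptide matching no database sequence keeps its PSM
#' accessions and a warning diagnostic is issued.
#'
#' @param accepted A tibble of accepted PSMs.
#' @param db A protein database tibble from [read_fasta()] (required when
#'   `remap = TRUE`).
#' @param remap Recompute accession sets by substring search?
#' @return A named list: peptide -> character vector of accessions.
#' @export
build_peptide_map <- function(accepted, db = NULL, remap = FALSE) {
  if (nrow(accepted) == 0) return(stats::setNames(list(), character(0)))
  peps <- unique(accepted$peptide)
  accs <- split_accessions(accepted$accessions)
  by_pep <- lapply(split(accs, factor(accepted$peptide, levels = peps)),
                   function(x) sort(unique(unlist(x))))
  map <- by_pep[peps]
  if (remap) {
    stopifnot(!is.null(db))
    seq_il <- chartr("I", "L", db$sequence)
    unmatched <- character(0)
    for (p in peps) {
      hit <- db$accession[grepl(chartr("I", "L", p), seq_il, fixed = TRUE)]
      if (length(hit) > 0) {
        map[[p]] <- sort(unique(hit))
      } else {
        unmatched <- c(unmatched, p)
      }
    }
    if (length(unmatched) > 0) {
      warning(sprintf("%d peptide(s) matched no database sequence; PSM %s",
                      length(unmatched),
                      "accessions retained for these peptides"),
              call. = FALSE)
    }
  }
  map
}

#' Collapse proteins into parsimony groups
#'
#' Proteins whose accepted-peptide sets are identical are merged into one
#' group (they are indistinguishable by MS/MS evidence); a protein whose
#' peptide set is a strict subset of another protein's is absorbed into the
#' subsuming protein's group and recorded in `subsumed_members`. Peptides
#' shared between distinct surviving groups are assigned for counting by the
#' razor rule: to the group with more distinct peptides, ties broken by the
#' lexicographically smallest representative. Every accepted PSM is counted
#' exactly once, so the group spectral counts sum to the number of accepted
#' PSMs.
#'
#' @param map A peptide-to-protein map from [build_peptide_map()].
#' @param psms The accepted PSM tibble the map was built from.
#' @return A tibble of protein groups with columns `representative`,
#'   `members` (list), `subsumed_members` (list), `distinct_peptides` (list),
#'   `n_peptides`, `spectral_count`, `peptide_probs` (list: best per-peptide
#'   probability, `NA` when no PSM carried one) and `protein_probability`
#'   (`NA`, filled by [accept_proteins()]), sorted by decreasing
#'   `spectral_count` then representative.
#' @export
group_by_parsimony <- function(map, psms) {
  empty <- tibble::tibble(representative = character(0),
                          members = list(), subsumed_members = list(),
                          distinct_peptides = list(), n_peptides = integer(0),
                          spectral_count = integer(0), peptide_probs = list(),
                          protein_probability = numeric(0))
  if (length(map) == 0) return(empty)

  # invert: accession -> sorted peptide set
  pep_rep <- rep(names(map), lengths(map))
  acc_flat <- unlist(map, use.names = FALSE)
  prot2pep <- lapply(split(pep_rep, acc_flat), function(x) sort(unique(x)))

  # (a) merge identical peptide sets
  key <- vapply(prot2pep, paste, character(1), collapse = "\r")
  grp_of <- split(names(prot2pep), key)
  groups <- lapply(grp_of, function(members) {
    members <- sort(members)
    list(members = members,
         representative = members[1],
         peptides = prot2pep[[members[1]]],
         subsumed = character(0))
  })
  names(groups) <- vapply(groups, `[[`, character(1), "representative")

  # (b) absorb strict subsets; candidates found through shared peptides
  npep <- vapply(groups, function(g) length(g$peptides), integer(1))
  pep_owner <- split(
    rep(names(groups), npep),
    unlist(lapply(groups, `[[`, "peptides"), use.names = FALSE)
  )
  absorbed_into <- stats::setNames(rep(NA_character_, length(groups)),
                                   names(groups))
  for (g in names(groups)) {
    peps <- groups[[g]]$peptides
    cand <- setdiff(unique(unlist(pep_owner[peps], use.names = FALSE)), g)
    cand <- cand[npep[cand] > npep[g]]
    if (length(cand) == 0) next
    sup <- cand[vapply(cand, function(h) {
      all(peps %in% groups[[h]]$peptides)
    }, logical(1))]
    if (length(sup) == 0) next
    best <- sup[order(-npep[sup], sup)][1]
    absorbed_into[g] <- best
  }
  resolve <- function(g) {
    while (!is.na(absorbed_into[g])) g <- absorbed_into[g]
    g
  }
  for (g in names(groups)) {
    if (!is.na(absorbed_into[g])) {
      target <- resolve(g)
      groups[[target]]$subsumed <- c(groups[[target]]$subsumed,
                                     groups[[g]]$members)
    }
  }
  surviving <- names(groups)[is.na(absorbed_into)]
  groups <- groups[surviving]
  npep <- npep[surviving]

  # (d) razor assignment of peptides shared between surviving groups
  owner <- split(
    rep(names(groups), vapply(groups, function(g) length(g$peptides),
                              integer(1))),
    unlist(lapply(groups, `[[`, "peptides"), use.names = FALSE)
  )
  assigned <- vapply(owner, function(gs) {
    if (length(gs) == 1) return(gs)
    gs[order(-npep[gs], gs)][1]
  }, character(1))

  # spectral counts: each accepted PSM counted once via its peptide's group
  sc_by_pep <- table(psms$peptide)
  sc <- vapply(names(groups), function(g) {
    peps <- names(assigned)[assigned == g]
    sum(sc_by_pep[peps], na.rm = TRUE)
  }, numeric(1))

  # best per-peptide probability over PSMs
  best_prob <- tapply(psms$peptide_probability, psms$peptide,
                      function(p) if (all(is.na(p))) NA_real_ else {
                        max(p, na.rm = TRUE)
                      })

  out <- tibble::tibble(
    representative = unname(vapply(groups, `[[`, character(1),
                                   "representative")),
    members = unname(lapply(groups, `[[`, "members")),
    subsumed_members = unname(lapply(groups,
                                     function(g) sort(unique(g$subsumed)))),
    distinct_peptides = unname(lapply(groups, `[[`, "peptides")),
    n_peptides = unname(vapply(groups, function(g) length(g$peptides),
                               integer(1))),
    spectral_count = as.integer(unname(sc)),
    peptide_probs = unname(lapply(groups, function(g) {
      stats::setNames(as.numeric(best_prob[g$peptides]), g$peptides)
    })),
    protein_probability = NA_real_
  )
  out[order(-out$spectral_count, out$representative), ]
}

#' Apply the protein-level acceptance rule
#'
#' A group is kept iff it has at least `min_peptides` distinct accepted
#' peptides and its protein probability meets `min_probability`. The protein
#' probability is the independence combination `1 - prod(1 - p_i)` over the
#' group's distinct peptides' best peptide probabilities; peptides that never
#' carried a probability contribute `default_peptide_probability` (the
#' peptide-filter threshold they had to clear).
#'
#' @param groups Output of [group_by_parsimony()].
#' @param min_peptides Minimum distinct peptides (default 2).
#' @param min_probability Minimum protein probability (default 0.99).
#' @param default_peptide_probability Stand-in for absent peptide
#'   probabilities (default 0.95).
#' @return The accepted groups with `protein_probability` filled in.
#' @export
accept_proteins <- function(groups, min_peptides = 2, min_probability = 0.99,
                            default_peptide_probability = 0.95) {
  if (nrow(groups) == 0) return(groups)
  prob <- unname(vapply(groups$peptide_probs, function(p) {
    p[is.na(p)] <- default_peptide_probability
    1 - prod(1 - p)
  }, numeric(1)))
  groups$protein_probability <- prob
  # small tolerance so boundary cases (e.g. two 0.9 peptides giving 0.99)
  # are not lost to floating-point representation
  keep <- groups$n_peptides >= min_peptides &
    prob >= min_probability - 1e-9
  groups[keep, , drop = FALSE]
}

#' Write a protein-group report
#'
#' @param groups A group tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_groups_table <- function(groups, path) {
  out <- groups[, c("representative", "members", "n_peptides",
                    "spectral_count", "protein_probability",
                    "subsumed_members")]
  write_report(out, path)
}
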