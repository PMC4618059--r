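#' Partition enrichment hits into PDZ and non-PDZ sets
#'
#' Matches each hit's representative name against the annotation table, first
#' by exact name, then by synonym (case-insensitive; synonyms never shadow a
#' primary name). Names found nowhere in the table default to non-PDZ, with a
#' single consolidated warning so novel background identifications are
#' auditable.
#'
#' @param enrichment A tibble from [call_enrichment()] (only rows with
#'   `hit == TRUE` are used) or any tibble with `representative` and `hit`
#'   columns.
#' @param annotations An annotation tibble from [read_annotation_table()] /
#'   [pdz_reference()].
#' @param sample_id Label stored on the resulting hit set.
#' @param warn_unknown Warn about names absent from the annotation table?
#' @return A `hit_set` list with elements `sample_id`, `hits`, `pdz_hits`,
#'   `nonpdz_hits` (character vectors; the partition is disjoint and covers
#'   `hits`).
#' @export
annotate_hits <- function(enrichment, annotations,
                          sample_id = NA_character_, warn_unknown = TRUE) {
  hits <- if ("hit" %in% names(enrichment)) {
    enrichment$representative[enrichment$hit]
  } else {
    enrichment$representative
  }
  hits <- unique(hits)
  by_name <- stats::setNames(annotations$is_pdz, toupper(annotations$name))
  syn_tab <- lapply(seq_len(nrow(annotations)), function(i) {
    s <- annotations$synonyms[i]
    if (is.na(s) || s == "") return(character(0))
    toupper(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  by_syn <- stats::setNames(
    rep(annotations$is_pdz, lengths(syn_tab)),
    unlist(syn_tab)
  )
  # primary names win over synonym matches (e.g. a name reused as a synonym)
  by_syn <- by_syn[!names(by_syn) %in% names(by_name)]

  up <- toupper(hits)
  is_pdz <- by_name[up]
  use_syn <- is.na(is_pdz)
  is_pdz[use_syn] <- by_syn[up[use_syn]]
  unknown <- hits[is.na(is_pdz)]
  if (length(unknown) > 0 && warn_unknown) {
    warning(sprintf("%d hit(s) absent from the annotation table, %s: %s",
                    length(unknown), "classified non-PDZ",
                    paste(utils::head(unknown, 10), collapse = ", ")),
            call. = FALSE)
  }
  is_pdz[is.na(is_pdz)] <- FALSE
  structure(
    list(sample_id = sample_id,
         hits = hits,
         pdz_hits = hits[is_pdz],
         nonpdz_hits = hits[!is_pdz]),
    class = "hit_set"
  )
}

#' Venn decomposition of hit sets across samples
#'
#' Computes the full Venn decomposition (all `2^k - 1` cells) of `k` hit
#' sets. The cell shared by every sample is the interaction "fingerprint"
#' common to all lysates.
#'
#' @param hitsets A list of `hit_set` objects (>= 2) with distinct
#'   `sample_id`s.
#' @param set Which partition to intersect: `"pdz"` (default, the PDZ-hit
#'   sets), `"nonpdz"`, or `"all"`.
#' @return A tibble with one row per nonempty-signature cell: `signature`
#'   (sample ids joined with `&`), `n_samples`, `members` (list column),
#'   `n_members`. All `2^k - 1` signatures are present, empty cells included.
#'   The all-samples cell is also attached as `attr(x, "fingerprint")`.
#' @export
intersect_hitsets <- function(hitsets, set = c("pdz", "nonpdz", "all")) {
  set <- match.arg(set)
  stopifnot(length(hitsets) >= 2)
  ids <- vapply(hitsets, function(h) as.character(h$sample_id), character(1))
  if (anyDuplicated(ids) > 0) {
    stop("duplicate sample_id among hit sets: ", ids[duplicated(ids)][1],
         call. = FALSE)
  }
  field <- switch(set, pdz = "pdz_hits", nonpdz = "nonpdz_hits", all = "hits")
  sets <- lapply(hitsets, `[[`, field)
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  k <- length(ids)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    inside <- as.logical(combos[i, ])
    cell <- universe[apply(member, 1, function(m) all(m == inside))]
    tibble::tibble(signature = paste(ids[inside], collapse = "&"),
                   n_samples = sum(inside),
                   members = list(cell),
                   n_members = length(cell))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$n_samples, out$signature), ]
  attr(out, "fingerprint") <- out$members[[which(out$n_samples == k)[1]]]
  out
}

#' The all-samples cell of a Venn decomposition
#'
#' @param venn Output of [intersect_hitsets()].
#' @return Character vector of names common to every sample.
#' @export
venn_fingerprint <- function(venn) {
  attr(venn, "fingerprint")
}
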