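#' Normalized spectral counts for one sample
#'
#' nSC is the protein group's spectral count divided by the summed spectral
#' count of the entire sample (all accepted groups in that elution), so nSC
#' sums to 1 over the groups with nonzero counts.
#'
#' @param groups Accepted protein groups of one sample
#'   (from [accept_proteins()]).
#' @param sample_id Label of the sample.
#' @param condition One of `"plus"`, `"minus"`, `"iM"`, `"sM"`.
#' @return A `sample_quant` tibble with columns `representative`,
#'   `spectral_count`, `nsc`, and attributes `sample_id` and `condition`.
#' @export
compute_nsc <- function(groups, sample_id = NA_character_,
                        condition = NA_character_) {
  total <- sum(groups$spectral_count)
  if (nrow(groups) == 0 || total == 0) {
    stop("undefined normalization: sample ", sample_id,
         " has no nonzero spectral counts", call. = FALSE)
  }
  out <- tibble::tibble(
    representative = groups$representative,
    spectral_count = groups$spectral_count,
    nsc = groups$spectral_count / total
  )
  attr(out, "sample_id") <- sample_id
  attr(out, "condition") <- condition
  class(out) <- c("sample_quant", class(out))
  out
}

#' Call bait-specific enrichment against the resin-only control
#'
#' Joins the bait (`'+'`) and control (`'-'`) quantitations over the union of
#' protein groups (a group absent from one sample enters with SC = 0). The
#' enrichment ratio is `nsc_plus / nsc_minus`, `+Inf` for groups exclusive to
#' the bait sample, 0 for groups seen only in the control. A group is
#' `significant` when its raw bait-sample spectral count strictly exceeds
#' `sc_min`; the default hit rule additionally requires exclusivity
#' (`SC_minus == 0`), matching a screen whose hits were essentially absent
#' from the controls. Set a finite `ratio_min` for a tolerant re-analysis
#' that also accepts finite ratios at or above it.
#'
#' @param plus,minus `sample_quant` tibbles from [compute_nsc()].
#' @param sc_min Significance cut-off on the raw `'+'` spectral count
#'   (strict `>`, default 10; see [resolve_sc_min()] for per-sample
#'   overrides).
#' @param ratio_min Minimum finite ratio accepted as a hit
#'   (default `Inf`: only bait-exclusive groups are hits).
#' @return A tibble with one row per group, columns `representative`,
#'   `sc_plus`, `sc_minus`, `nsc_plus`, `nsc_minus`, `ratio`, `significant`,
#'   `exclusive_plus`, `hit`, sorted by (`exclusive_plus` desc, `ratio` desc,
#'   `sc_plus` desc).
#' @export
call_enrichment <- function(plus, minus, sc_min = 10, ratio_min = Inf) {
  stopifnot(sc_min > 0)
  reps <- union(plus$representative, minus$representative)
  idx_p <- match(reps, plus$representative)
  idx_m <- match(reps, minus$representative)
  pick <- function(q, idx, col, fill = 0) {
    v <- q[[col]][idx]
    v[is.na(idx)] <- fill
    v
  }
  sc_plus <- pick(plus, idx_p, "spectral_count")
  sc_minus <- pick(minus, idx_m, "spectral_count")
  nsc_plus <- pick(plus, idx_p, "nsc")
  nsc_minus <- pick(minus, idx_m, "nsc")
  ratio <- ifelse(nsc_minus > 0, nsc_plus / nsc_minus,
                  ifelse(sc_plus > 0, Inf, NA_real_))
  exclusive_plus <- sc_minus == 0 & sc_plus > 0
  significant <- sc_plus > sc_min
  hit <- significant & (exclusive_plus | (is.finite(ratio) &
                                            ratio >= ratio_min))
  out <- tibble::tibble(
    representative = reps,
    sc_plus = as.integer(sc_plus), sc_minus = as.integer(sc_minus),
    nsc_plus = nsc_plus, nsc_minus = nsc_minus,
    ratio = ratio, significant = significant,
    exclusive_plus = exclusive_plus, hit = hit
  )
  out[order(-out$exclusive_plus, -ifelse(is.na(out$ratio), -Inf, out$ratio),
            -out$sc_plus, out$representative), ]
}

#' Resolve the per-sample significance cut-off
#'
#' The default spectral-count significance cut-off is 10; individual samples
#' may override it (e.g. a cut-off of 20 used for one lysate to obtain a
#' smaller hit set).
#'
#' @param sample_id Sample label to look up.
#' @param default Default cut-off (strict `>`).
#' @param overrides Named list/vector of per-sample cut-offs.
#' @return The cut-off for `sample_id`.
#' @export
resolve_sc_min <- function(sample_id, default = 10, overrides = list()) {
  value <- if (!is.null(overrides[[sample_id]])) {
    overrides[[sample_id]]
  } else {
    default
  }
  if (!is.numeric(value) || length(value) != 1 || value <= 0) {
    stop("config error: sc_min must be a positive number, got ",
         deparse(value), " for sample ", sample_id, call. = FALSE)
  }
  value
}

#' Write an enrichment report
#'
#' @param enrichment Tibble from [call_enrichment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(enrichment, path) {
  write_report(enrichment, path)
}
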