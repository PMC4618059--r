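#' Round half-up to a fixed number of decimals
#'
#' Display rounding for reported fold-enrichment values (0.25 -> 0.3 at one
#' decimal), as opposed to the round-half-even rule of [round()].
#'
#' @param x Numeric vector (nonnegative use is intended).
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

.fraction_statuses <- c("ratio", "only_iM", "only_sM", "not_significant")

#' Per-construct iM/sM fraction ratio
#'
#' For one receptor construct, joins the detergent-insoluble (iM) and
#' detergent-soluble (sM) membrane-fraction quantitations and classifies each
#' protein:
#' \itemize{
#'   \item `only_iM` when SC(iM) strictly exceeds `sc_min` and SC(sM) is 0;
#'   \item `only_sM` symmetric;
#'   \item `not_significant` when SC is below `sc_min` in both fractions;
#'   \item otherwise `ratio`, with value `nsc_iM / nsc_sM`.
#' }
#' The boundary case not covered by these classes (one fraction exactly at
#' `sc_min`, the other 0, so the ratio denominator vanishes) is classified
#' `not_significant` as the conservative tie-break.
#'
#' @param quant_im,quant_sm `sample_quant` tibbles for the iM and sM
#'   fractions of one construct.
#' @param sc_min Significance cut-off (default 10).
#' @return A ratio-map tibble with columns `name`, `status`, `ratio` (`NA`
#'   unless `status == "ratio"`), `sc_im`, `sc_sm`.
#' @export
fraction_ratio <- function(quant_im, quant_sm, sc_min = 10) {
  stopifnot(sc_min > 0)
  reps <- union(quant_im$representative, quant_sm$representative)
  idx_i <- match(reps, quant_im$representative)
  idx_s <- match(reps, quant_sm$representative)
  pick <- function(q, idx, col) {
    v <- q[[col]][idx]
    v[is.na(idx)] <- 0
    v
  }
  sc_i <- pick(quant_im, idx_i, "spectral_count")
  sc_s <- pick(quant_sm, idx_s, "spectral_count")
  nsc_i <- pick(quant_im, idx_i, "nsc")
  nsc_s <- pick(quant_sm, idx_s, "nsc")

  status <- rep("not_significant", length(reps))
  status[sc_i > sc_min & sc_s == 0] <- "only_iM"
  status[sc_s > sc_min & sc_i == 0] <- "only_sM"
  usable <- status == "not_significant" & !(sc_i < sc_min & sc_s < sc_min) &
    nsc_s > 0
  status[usable] <- "ratio"
  ratio <- ifelse(status == "ratio", nsc_i / nsc_s, NA_real_)
  tibble::tibble(name = reps, status = status, ratio = ratio,
                 sc_im = as.integer(sc_i), sc_sm = as.integer(sc_s))
}

#' Fold enrichment of WT over the PDZ-motif-deleted construct
#'
#' For every protein in the merged name universe, the fold enrichment is
#' `FE = (iM/sM ratio in WT) / (iM/sM ratio in the deletion construct)`.
#' FE is defined only when both constructs carry a numeric ratio; any status
#' class on either side (`only_iM`, `only_sM`, `not_significant`) leaves FE
#' undefined and the display column shows an em dash. Displayed FE is rounded
#' half-up to one decimal; full precision is kept in `fold_enrichment`.
#'
#' @param wt,dpdz Ratio-map tibbles from [fraction_ratio()] (or the packaged
#'   printed table via [membrane_fraction_table()]).
#' @return A tibble with columns `name`, `ratio_wt`, `ratio_dpdz`,
#'   `status_wt`, `status_dpdz`, `fold_enrichment`, `display_fe`.
#' @export
fold_enrichment <- function(wt, dpdz) {
  stopifnot(all(wt$status %in% .fraction_statuses),
            all(dpdz$status %in% .fraction_statuses))
  names_all <- union(wt$name, dpdz$name)
  side <- function(map, col) {
    idx <- match(names_all, map$name)
    v <- map[[col]][idx]
    if (col == "status") v[is.na(idx)] <- "not_significant"
    v
  }
  ratio_wt <- side(wt, "ratio")
  ratio_dpdz <- side(dpdz, "ratio")
  status_wt <- side(wt, "status")
  status_dpdz <- side(dpdz, "status")
  defined <- status_wt == "ratio" & status_dpdz == "ratio"
  fe <- ifelse(defined, ratio_wt / ratio_dpdz, NA_real_)
  display <- ifelse(defined,
                    sprintf("%.1f", round_half_up(fe, 1)),
                    "—")
  out <- tibble::tibble(name = names_all,
                        ratio_wt = ratio_wt, ratio_dpdz = ratio_dpdz,
                        status_wt = status_wt, status_dpdz = status_dpdz,
                        fold_enrichment = fe, display_fe = display)
  out[order(-ifelse(is.na(out$fold_enrichment), -Inf, out$fold_enrichment),
            out$name), ]
}

#' Direct binders from fold-enrichment records
#'
#' Proteins whose defined fold enrichment strictly exceeds `fe_min` are
#' called direct (PDZ-motif-dependent) binders. Records with undefined FE
#' (a status class in either construct) are never called.
#'
#' @param records Tibble from [fold_enrichment()].
#' @param fe_min Fold-enrichment threshold (default 2.0, strict `>`).
#' @return Sorted character vector of names.
#' @export
classify_direct_binders <- function(records, fe_min = 2.0) {
  sort(records$name[!is.na(records$fold_enrichment) &
                      records$fold_enrichment > fe_min])
}

#' Write a fold-enrichment report
#'
#' Column order follows the published validation table: name, WT iM/sM,
#' deletion-construct iM/sM, fold enrichment (display-rounded).
#'
#' @param records Tibble from [fold_enrichment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fold_enrichment_table <- function(records, path) {
  out <- tibble::tibble(
    name = records$name,
    wt_im_sm = ifelse(records$status_wt == "ratio",
                      as.character(signif(records$ratio_wt, 4)),
                      records$status_wt),
    dpdz_im_sm = ifelse(records$status_dpdz == "ratio",
                        as.character(signif(records$ratio_dpdz, 4)),
                        records$status_dpdz),
    fold_enrichment = records$display_fe
  )
  write_report(out, path, display_cols = "fold_enrichment")
}

#' Count checks against supplementary protein tables
#'
#' Given locally supplied tab-separated exports of the deposited
#' supplementary protein tables (one row per protein, with at minimum a
#' `name` column, and for the validation table spectral-count columns), this
#' recomputes the headline counts: total proteins per table and the number of
#' PDZ-annotated proteins passing the spectral-count significance filter in
#' the validation table. The deposited tables are not shipped with the
#' package; pass paths to your own exports.
#'
#' @param s1_path TSV export of the pull-down protein list (row per protein).
#' @param s4_path TSV export of the validation protein list; must contain
#'   `name` and one or more `sc_*` spectral-count columns.
#' @param annotations Annotation tibble (default [pdz_reference()]).
#' @param sc_min Significance cut-off applied to the maximum spectral count
#'   across the `sc_*` columns (strict `>`, default 10).
#' @return A list with `n_s1`, `n_s4`, `n_pdz_significant_s4`.
#' @export
check_supplementary_counts <- function(s1_path, s4_path,
                                       annotations = pdz_reference(),
                                       sc_min = 10) {
  s1 <- utils::read.delim(s1_path, sep = "\t", stringsAsFactors = FALSE)
  s4 <- utils::read.delim(s4_path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot("name" %in% names(s1), "name" %in% names(s4))
  sc_cols <- grep("^sc_", names(s4), value = TRUE)
  stopifnot(length(sc_cols) > 0)
  sc_max <- do.call(pmax, c(s4[sc_cols], na.rm = TRUE))
  significant <- s4$name[sc_max > sc_min]
  pdz_names <- toupper(annotations$name[annotations$is_pdz])
  syn_pdz <- unlist(lapply(which(annotations$is_pdz), function(i) {
    s <- annotations$synonyms[i]
    if (is.na(s) || s == "") character(0) else {
      toupper(strsplit(s, ";", fixed = TRUE)[[1]])
    }
  }))
  is_pdz <- toupper(significant) %in% union(pdz_names, syn_pdz)
  list(n_s1 = nrow(s1), n_s4 = nrow(s4),
       n_pdz_significant_s4 = sum(is_pdz))
}
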