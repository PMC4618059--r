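#' Peptide-level acceptance criteria
#'
#' Bundles the per-engine score thresholds used to accept peptide
#' identifications. The defaults are the thresholds of the original screen:
#' Mascot ion score strictly greater than 40; Sequest requires deltaCn
#' strictly greater than 0.10 *and* a charge-dependent XCorr strictly greater
#' than 1.5 / 2.0 / 2.2 / 2.5 for 1+ / 2+ / 3+ / 4+ precursors (charges above
#' 4 use the 4+ threshold); X!Tandem requires -log10(Expect) strictly greater
#' than 2.0.
#'
#' The published text also states a PeptideProphet probability cut-off of
#' "greater than 0.1%", which would accept essentially everything and is
#' almost certainly a misprint; the probability threshold is therefore an
#' explicit knob defaulting to 0.95 and applied as `probability >= min` when
#' a probability is present.
#'
#' @param mascot_min Mascot ion-score threshold (strict `>`).
#' @param deltacn_min Sequest deltaCn threshold (strict `>`).
#' @param xcorr_min_by_charge Named numeric vector of XCorr thresholds for
#'   charges `"1"`..`"4"`; charges above 4 use the `"4"` entry.
#' @param xtandem_min_neg_log_e X!Tandem -log10(Expect) threshold (strict `>`).
#' @param peptide_probability_min Probability threshold in `[0, 1]`, applied
#'   as `>=` to records that carry a probability.
#' @param engine_combination `"any_engine"` (default: one passing engine
#'   suffices) or `"all_present_engines"` (every engine that scored the
#'   spectrum must pass).
#' @return A `filter_criteria` list.
#' @export
filter_criteria <- function(mascot_min = 40,
                            deltacn_min = 0.10,
                            xcorr_min_by_charge = c(`1` = 1.5, `2` = 2.0,
                                                    `3` = 2.2, `4` = 2.5),
                            xtandem_min_neg_log_e = 2.0,
                            peptide_probability_min = 0.95,
                            engine_combination = c("any_engine",
                                                   "all_present_engines")) {
  engine_combination <- match.arg(engine_combination)
  stopifnot(
    is.finite(mascot_min), is.finite(deltacn_min),
    is.finite(xtandem_min_neg_log_e),
    all(as.character(1:4) %in% names(xcorr_min_by_charge)),
    all(is.finite(xcorr_min_by_charge)),
    is.finite(peptide_probability_min),
    peptide_probability_min >= 0, peptide_probability_min <= 1
  )
  structure(
    list(mascot_min = mascot_min,
         deltacn_min = deltacn_min,
         xcorr_min_by_charge = xcorr_min_by_charge,
         xtandem_min_neg_log_e = xtandem_min_neg_log_e,
         peptide_probability_min = peptide_probability_min,
         engine_combination = engine_combination),
    class = "filter_criteria"
  )
}

#' Does an engine support a PSM?
#'
#' Vectorized over the rows of a PSM table. A record whose score for the
#' requested engine is absent gets `FALSE` (that engine offers no support);
#' all threshold comparisons are strict per the criteria wording. Sequest
#' support requires both the deltaCn and the charge-matched XCorr threshold.
#'
#' @param psms A PSM tibble.
#' @param criteria A [filter_criteria()] object.
#' @param engine One of `"mascot"`, `"sequest"`, `"xtandem"`.
#' @return Logical vector, one element per PSM row.
#' @export
passes_engine <- function(psms, criteria, engine = c("mascot", "sequest",
                                                     "xtandem")) {
  engine <- match.arg(engine)
  switch(engine,
    mascot = {
      s <- psms$mascot_ion_score
      !is.na(s) & s > criteria$mascot_min
    },
    sequest = {
      xc <- psms$sequest_xcorr
      dc <- psms$sequest_deltacn
      bucket <- as.character(pmin(pmax(psms$charge, 1L), 4L))
      thr <- unname(criteria$xcorr_min_by_charge[bucket])
      !is.na(xc) & !is.na(dc) & dc > criteria$deltacn_min & xc > thr
    },
    xtandem = {
      s <- psms$xtandem_neg_log_e
      !is.na(s) & s > criteria$xtandem_min_neg_log_e
    }
  )
}

#' Apply the peptide acceptance criteria to a PSM table
#'
#' A PSM is accepted iff its PeptideProphet-style probability (when present)
#' meets `peptide_probability_min` *and* it has engine support under
#' `engine_combination`. The partition is exhaustive and order-preserving.
#'
#' @param psms A PSM tibble (as from [read_psm_table()]).
#' @param criteria A [filter_criteria()] object.
#' @return A list with elements `accepted` (PSM tibble) and `rejected`
#'   (PSM tibble with an extra `reason` column, one of `"probability"`,
#'   `"engine_support"`).
#' @export
filter_psms <- function(psms, criteria = filter_criteria()) {
  if (nrow(psms) == 0) {
    rej <- psms
    rej$reason <- character(0)
    return(list(accepted = psms, rejected = rej))
  }
  prob <- psms$peptide_probability
  prob_ok <- is.na(prob) | prob >= criteria$peptide_probability_min

  pass <- cbind(mascot  = passes_engine(psms, criteria, "mascot"),
                sequest = passes_engine(psms, criteria, "sequest"),
                xtandem = passes_engine(psms, criteria, "xtandem"))
  present <- cbind(mascot  = !is.na(psms$mascot_ion_score),
                   sequest = !is.na(psms$sequest_xcorr),
                   xtandem = !is.na(psms$xtandem_neg_log_e))
  engine_ok <- if (criteria$engine_combination == "any_engine") {
    rowSums(pass) > 0
  } else {
    rowSums(present) > 0 & rowSums(present & !pass) == 0
  }

  keep <- prob_ok & engine_ok
  rejected <- psms[!keep, , drop = FALSE]
  rejected$reason <- ifelse(!prob_ok[!keep], "probability", "engine_support")
  list(accepted = psms[keep, , drop = FALSE], rejected = rejected)
}
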