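test_that("engine thresholds are strict at every published boundary", {
  crit <- filter_criteria()
  at <- function(...) make_psm(...)

  expect_true(passes_engine(at(mascot_ion_score = 41), crit, "mascot"))
  expect_false(passes_engine(at(mascot_ion_score = 40), crit, "mascot"))

  # charge-dependent XCorr, both Sequest conditions required
  cases <- data.frame(charge = c(1, 2, 3, 4, 6),
                      thr = c(1.5, 2.0, 2.2, 2.5, 2.5))
  for (i in seq_len(nrow(cases))) {
    ch <- cases$charge[i]
    thr <- cases$thr[i]
    expect_true(passes_engine(
      at(charge = ch, sequest_xcorr = thr + 0.1, sequest_deltacn = 0.15),
      crit, "sequest"), info = paste("charge", ch))
    expect_false(passes_engine(
      at(charge = ch, sequest_xcorr = thr, sequest_deltacn = 0.15),
      crit, "sequest"), info = paste("charge", ch, "at boundary"))
  }
  expect_false(passes_engine(
    at(charge = 3, sequest_xcorr = 2.3, sequest_deltacn = 0.10),
    crit, "sequest"))
  expect_false(passes_engine(
    at(charge = 3, sequest_xcorr = 2.3, sequest_deltacn = NA_real_),
    crit, "sequest"))

  expect_true(passes_engine(at(xtandem_neg_log_e = 2.1), crit, "xtandem"))
  expect_false(passes_engine(at(xtandem_neg_log_e = 2.0), crit, "xtandem"))
  # absent score means no support from that engine
  expect_false(passes_engine(at(mascot_ion_score = NA_real_), crit,
                             "mascot"))
})

test_that("filter_psms combines probability and engine support exhaustively", {
  crit <- filter_criteria()
  psms <- dplyr::bind_rows(
    make_psm(spectrum_id = "mascot_only", mascot_ion_score = 50),
    make_psm(spectrum_id = "low_prob", mascot_ion_score = 50,
             sequest_xcorr = 3, sequest_deltacn = 0.2,
             xtandem_neg_log_e = 3, peptide_probability = 0.10),
    make_psm(spectrum_id = "no_support", mascot_ion_score = 30)
  )
  out <- filter_psms(psms, crit)
  expect_equal(out$accepted$spectrum_id, "mascot_only")
  expect_equal(nrow(out$accepted) + nrow(out$rejected), nrow(psms))
  expect_equal(out$rejected$reason[out$rejected$spectrum_id == "low_prob"],
               "probability")
  expect_equal(out$rejected$reason[out$rejected$spectrum_id == "no_support"],
               "engine_support")

  empty <- filter_psms(psms[0, ], crit)
  expect_equal(nrow(empty$accepted), 0)
  expect_equal(nrow(empty$rejected), 0)
})

test_that("all_present_engines is stricter and requires every scored engine to pass", {
  strict <- filter_criteria(engine_combination = "all_present_engines")
  both_pass <- make_psm(mascot_ion_score = 50, xtandem_neg_log_e = 3)
  one_fails <- make_psm(mascot_ion_score = 50, xtandem_neg_log_e = 1)
  expect_equal(nrow(filter_psms(both_pass, strict)$accepted), 1)
  expect_equal(nrow(filter_psms(one_fails, strict)$accepted), 0)
  # same record passes under any_engine
  expect_equal(nrow(filter_psms(one_fails, filter_criteria())$accepted), 1)
})

test_that("filtering agrees with a brute-force oracle and is threshold-monotone", {
  for (seed in 1:5) {
    psms <- random_psms(200, seed)
    for (combo in c("any_engine", "all_present_engines")) {
      crit <- filter_criteria(engine_combination = combo)
      got <- filter_psms(psms, crit)
      expect_equal(nrow(got$accepted) + nrow(got$rejected), nrow(psms))
      expect_equal(got$accepted$spectrum_id,
                   psms$spectrum_id[oracle_filter(psms, crit)])
    }
    # raising any threshold never grows the accepted set
    base <- filter_psms(psms, filter_criteria())$accepted$spectrum_id
    tighter <- list(
      filter_criteria(mascot_min = 60),
      filter_criteria(deltacn_min = 0.2),
      filter_criteria(xcorr_min_by_charge = c(`1` = 2, `2` = 2.5, `3` = 2.7,
                                              `4` = 3)),
      filter_criteria(xtandem_min_neg_log_e = 3),
      filter_criteria(peptide_probability_min = 0.99)
    )
    for (crit in tighter) {
      expect_true(all(filter_psms(psms, crit)$accepted$spectrum_id %in%
                        base))
    }
  }
})
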