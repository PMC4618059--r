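small_cfg <- function(seed = 3, n_background = 60, n_true_interactors = 8,
                      ...) {
  synthetic_config(seed = seed, n_background = n_background,
                   n_true_interactors = n_true_interactors, ...)
}

test_that("tryptic digestion cleaves after K/R but not before proline", {
  expect_equal(digest_tryptic("AAAAKGGGGGRCCCCCC", c(5, 25)),
               c("AAAAK", "GGGGGR", "CCCCCC"))
  # KP is not a cleavage site
  expect_equal(digest_tryptic("AAAAKPGGGGR", c(5, 25)), c("AAAAKPGGGGR"))
  # length filter applies
  expect_equal(digest_tryptic("AAKCCCCCCK", c(5, 8)), "CCCCCCK")
})

test_that("simulated proteomes have the configured size, labels and peptides", {
  prot <- simulate_proteome(synthetic_config(seed = 1))
  expect_equal(nrow(prot$db), 925)  # 900 background + 25 interactors
  expect_equal(sum(prot$truth$role == "true_interactor"), 25)
  expect_equal(sum(prot$truth$is_pdz), 15)
  expect_true(all(prot$truth$accession[prot$truth$is_pdz] %in%
                    pdz_reference()$name))
  expect_true(all(lengths(prot$peptides) > 0))
  # generated sequences digest back to their own peptide inventory
  i <- which(prot$truth$role == "true_interactor")[1]
  expect_setequal(
    digest_tryptic(prot$db$sequence[i], c(7, 25)),
    prot$peptides[[prot$db$accession[i]]]
  )
  expect_error(synthetic_config(n_background = 0), "n_background")
})

test_that("one seed gives byte-identical simulator output", {
  cfg <- small_cfg(seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_pulldown(cfg, outdir = d1)
  simulate_pulldown(cfg, outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the data
  other <- simulate_pulldown(small_cfg(seed = 10))
  first <- simulate_pulldown(cfg)
  expect_false(identical(first$plus$peptide, other$plus$peptide))
})

test_that("pull-down truth sidecars separate signal from background", {
  cfg <- small_cfg(seed = 7)
  sim <- simulate_pulldown(cfg)
  truth <- sim$truth_proteins
  true_acc <- truth$accession[truth$role == "true_interactor"]

  count_sc <- function(psms) {
    tp <- sim$truth_psms[sim$truth_psms$sample_id == psms$sample_id[1], ]
    src <- tp$source_accession[tp$correct]
    sum(src %in% true_acc)
  }
  # aggregate spectra of true interactors dominate in '+'
  expect_gt(count_sc(sim$plus), count_sc(sim$minus))

  # with no incorrect PSMs every spectrum maps to its source protein
  clean <- simulate_pulldown(small_cfg(seed = 5, incorrect_psm_rate = 0))
  expect_true(all(clean$truth_psms$correct))
  expect_equal(clean$plus$accessions,
               clean$truth_psms$source_accession[
                 clean$truth_psms$sample_id == "pulldown_plus"])
})

test_that("zero-variance fractionation yields the target fold enrichment exactly", {
  cfg <- small_cfg(seed = 2)
  frac <- simulate_fractionation(cfg, zero_variance = TRUE)
  fq <- lapply(frac$samples, quantify_sample)
  fe <- fold_enrichment(fraction_ratio(fq$wt_iM, fq$wt_sM),
                        fraction_ratio(fq$dpdz_iM, fq$dpdz_sM))
  binders <- frac$truth_proteins$accession[frac$truth_proteins$is_binder]
  expect_equal(fe$fold_enrichment[match(binders, fe$name)],
               rep(cfg$validation_fe, length(binders)), tolerance = 1e-9)
  # non-binder panel proteins sit at FE 1 exactly
  panel_fe1 <- frac$truth_proteins$accession[
    frac$truth_proteins$in_panel & !frac$truth_proteins$is_binder]
  expect_equal(fe$fold_enrichment[match(panel_fe1, fe$name)],
               rep(1, length(panel_fe1)), tolerance = 1e-9)
})

test_that("a null pull-down (no enrichment) produces essentially no hits", {
  cfg <- small_cfg(seed = 21, enrichment_factor = 1,
                   n_background = 300, n_true_interactors = 10)
  sim <- simulate_pulldown(cfg)
  enr <- call_enrichment(quantify_sample(sim$plus),
                         quantify_sample(sim$minus))
  bg <- sim$truth_proteins$accession[
    sim$truth_proteins$role == "background"]
  flagged_bg <- sum(enr$representative[enr$hit] %in% bg)
  expect_lte(flagged_bg / length(bg), 0.01)
})
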