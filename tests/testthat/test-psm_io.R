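test_that("a well-formed PSM table reads back in file order", {
  psms <- make_psm(n = 3, spectrum_id = c("a", "b", "c"),
                   peptide = c("ELVISLK", "PRESLEYK", "GRACELANDK"),
                   peptide_probability = c(0.99, NA, 0.97))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(psms, path)
  back <- read_psm_table(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$spectrum_id, c("a", "b", "c"))
  expect_equal(back[names(psms)], psms, ignore_attr = TRUE)
  expect_equal(nrow(attr(back, "rejected")), 0)
})

test_that("invalid rows are rejected with row-numbered diagnostics, never silently", {
  psms <- dplyr::bind_rows(
    make_psm(spectrum_id = "ok1"),
    make_psm(spectrum_id = "bad_charge", charge = 0L),
    make_psm(spectrum_id = "no_score", mascot_ion_score = NA_real_),
    make_psm(spectrum_id = "short_pep", peptide = "ELK"),
    make_psm(spectrum_id = "odd_residue", peptide = "ELVIBLK"),
    make_psm(spectrum_id = "ok2")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(psms, path)
  expect_warning(back <- read_psm_table(path), "rejected 4 PSM row")
  rej <- attr(back, "rejected")
  expect_equal(nrow(back) + nrow(rej), 6)
  expect_equal(back$spectrum_id, c("ok1", "ok2"))
  expect_equal(rej$row, c(2L, 3L, 4L, 5L))
  expect_match(rej$reason[rej$spectrum_id == "bad_charge"], "charge")
  expect_match(rej$reason[rej$spectrum_id == "no_score"], "engine score")
})

test_that("structural problems abort the read with a named diagnosis", {
  psms <- make_psm(n = 2, spectrum_id = c("x", "x"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(psms, path)
  expect_error(read_psm_table(path), "duplicate.*x")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  broken <- make_psm()
  broken$charge <- NULL
  utils::write.table(broken, path2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_psm_table(path2), "missing mandatory column.*charge")
})

test_that("FASTA databases read with normalized sequences and unique accessions", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 first protein", "elvislk", ">P2", "PRESLEYKGR"), path)
  db <- read_fasta(path)
  expect_equal(nrow(db), 2)
  expect_equal(db$accession, c("P1", "P2"))
  expect_equal(db$sequence[1], "ELVISLK")
  expect_equal(db$description[1], "first protein")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "AAAAA", ">P1 again", "CCCCC"), dup)
  expect_error(read_fasta(dup), "duplicated accession: P1")
})

test_that("FASTA writing round-trips through read_fasta", {
  db <- tibble::tibble(accession = c("A1", "B2"),
                       description = c("alpha", ""),
                       sequence = c(strrep("ACDEFGHIK", 20), "MKLVR"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(db, path)
  back <- read_fasta(path)
  expect_equal(back$accession, db$accession)
  expect_equal(back$sequence, db$sequence)
})

test_that("the packaged PDZ reference reproduces the published domain inventory", {
  ann <- pdz_reference()
  pulldown <- ann[ann$source == "pulldown", ]
  expect_equal(nrow(pulldown), 26)
  expect_true(all(pulldown$is_pdz))
  expect_equal(ann$n_pdz_domains[ann$name == "MPDZ"], 13L)
  expect_equal(ann$n_pdz_domains[ann$name == "INADL"], 10L)
  expect_equal(ann$n_pdz_domains[ann$name == "DLG1"], 3L)
  expect_true(all(c("NEB1", "NEB2", "PDZD8") %in%
                    ann$name[ann$source == "validation"]))
})

test_that("annotation tables enforce the PDZ-count invariant", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tis_pdz\tn_pdz_domains",
               "GOOD\tFALSE\t0",
               "BAD\tTRUE\t0"), path)
  expect_error(read_annotation_table(path), "BAD")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tis_pdz\tn_pdz_domains", "GOOD\tFALSE\t0"), path2)
  ann <- read_annotation_table(path2)
  expect_equal(nrow(ann), 1)
  expect_false(ann$is_pdz)
})
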