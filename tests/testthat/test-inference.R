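test_that("peptide maps come from PSM accessions or database remapping", {
  psms <- dplyr::bind_rows(
    make_psm(spectrum_id = "a", peptide = "SAMPLEK", accessions = "P1"),
    make_psm(spectrum_id = "b", peptide = "TWLNSNK", accessions = "P2;P3")
  )
  map <- build_peptide_map(psms)
  expect_equal(map$SAMPLEK, "P1")
  expect_equal(map$TWLNSNK, c("P2", "P3"))

  db <- tibble::tibble(
    accession = c("P1", "P2", "P3"),
    description = "",
    sequence = c("MMMSAMPLEKMMM", "AATWLNSNKAA", "CCTWLNSNKCC")
  )
  remapped <- build_peptide_map(psms, db = db, remap = TRUE)
  expect_equal(remapped$SAMPLEK, "P1")
  expect_equal(remapped$TWLNSNK, c("P2", "P3"))

  # I/L equivalence: isobaric residues are indistinguishable by MS/MS
  il <- make_psm(spectrum_id = "c", peptide = "LLKAYR", accessions = "P9")
  db_il <- tibble::tibble(accession = "Q1", description = "",
                          sequence = "MMILKAYRMM")
  map_il <- build_peptide_map(il, db = db_il, remap = TRUE)
  expect_equal(map_il$LLKAYR, "Q1")

  # unmatched peptides keep their PSM accessions with a warning
  expect_warning(
    kept <- build_peptide_map(il, db = db, remap = TRUE),
    "matched no database sequence"
  )
  expect_equal(kept$LLKAYR, "P9")
})

test_that("parsimony merges indistinguishable proteins and absorbs subsets", {
  # identical peptide sets collapse to one group
  map <- list(PEPONEK = c("A", "B"), PEPTWOK = c("A", "B"))
  groups <- group_by_parsimony(map, psms_for_map(map))
  expect_equal(nrow(groups), 1)
  expect_equal(groups$members[[1]], c("A", "B"))
  expect_equal(groups$representative, "A")

  # a strict-subset protein is absorbed and flagged
  map2 <- list(PEPONEK = "A", PEPTWOK = c("A", "B"), PEPTHRK = "A")
  groups2 <- group_by_parsimony(map2, psms_for_map(map2))
  expect_equal(nrow(groups2), 1)
  expect_equal(groups2$representative, "A")
  expect_equal(groups2$subsumed_members[[1]], "B")
  expect_equal(groups2$n_peptides, 3L)
})

test_that("shared peptides are razor-assigned once and spectra are conserved", {
  # A:{p1,p2}, B:{p2,p3}; p2 carries 4 spectra
  map <- list(PEPAONEK = "A", PEPSHAREDK = c("A", "B"), PEPBONEK = "B")
  psms <- psms_for_map(map, counts = c(1L, 4L, 1L))
  groups <- group_by_parsimony(map, psms)
  expect_equal(nrow(groups), 2)
  # tie on peptide count resolves to the lexicographically smaller rep
  sc <- stats::setNames(groups$spectral_count, groups$representative)
  expect_equal(sc[["A"]], 5L)
  expect_equal(sc[["B"]], 1L)
  expect_equal(sum(groups$spectral_count), nrow(psms))
})

test_that("protein acceptance needs two peptides and 99% combined probability", {
  one_pep <- list(PEPONLYK = "A")
  g1 <- group_by_parsimony(one_pep,
                           psms_for_map(one_pep, counts = 5L) |>
                             dplyr::mutate(peptide_probability = 1.0))
  expect_equal(nrow(accept_proteins(g1)), 0)

  # 1 - (1 - 0.9)^2 = 0.99 sits exactly at the acceptance boundary
  map <- list(PEPONEK = "A", PEPTWOK = "A")
  psms <- psms_for_map(map) |> dplyr::mutate(peptide_probability = 0.9)
  g2 <- group_by_parsimony(map, psms)
  kept <- accept_proteins(g2)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$protein_probability, 1 - (1 - 0.9) * (1 - 0.9))

  slightly_less <- accept_proteins(
    group_by_parsimony(map, psms_for_map(map) |>
                         dplyr::mutate(peptide_probability = 0.89)))
  expect_equal(nrow(slightly_less), 0)

  # absent probabilities stand in at the peptide-filter threshold
  g3 <- group_by_parsimony(map, psms_for_map(map))
  expect_equal(accept_proteins(g3)$protein_probability, 1 - 0.05^2)
  expect_equal(nrow(accept_proteins(g3[0, ])), 0)
})

test_that("parsimony matches the brute-force oracle on random small instances", {
  for (seed in 1:25) {
    map <- random_instance(seed)
    psms <- psms_for_map(map, counts = sample(1:5, length(map),
                                              replace = TRUE))
    groups <- group_by_parsimony(map, psms)
    oracle <- oracle_parsimony(map)

    expect_setequal(groups$representative, names(oracle))
    for (i in seq_len(nrow(groups))) {
      r <- groups$representative[i]
      expect_equal(groups$members[[i]], oracle[[r]]$members)
      expect_equal(groups$distinct_peptides[[i]], oracle[[r]]$peptides)
    }
    # spectral counts conserve accepted spectra and match razor assignment
    expect_equal(sum(groups$spectral_count), nrow(psms))
    sc_by_pep <- table(psms$peptide)
    for (i in seq_len(nrow(groups))) {
      r <- groups$representative[i]
      expect_equal(groups$spectral_count[i],
                   sum(sc_by_pep[oracle[[r]]$razor_peptides]) |>
                     as.integer())
    }
    # every accepted peptide is covered by a surviving group
    covered <- unique(unlist(groups$distinct_peptides))
    expect_true(all(names(map) %in% covered))

    # idempotence: regrouping the surviving groups changes nothing
    map2 <- list()
    for (i in seq_len(nrow(groups))) {
      for (p in groups$distinct_peptides[[i]]) {
        map2[[p]] <- sort(c(map2[[p]], groups$representative[i]))
      }
    }
    groups2 <- group_by_parsimony(map2, psms)
    expect_setequal(groups2$representative, groups$representative)
    expect_equal(sum(groups2$spectral_count), nrow(psms))
  }
})
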