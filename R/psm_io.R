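#' Column registry of the flat PSM table dialect
#'
#' The pipeline consumes peptide-spectrum matches (PSMs) as a flat
#' tab-separated table, one row per identified spectrum, carrying the scores
#' of every search engine that identified it. Absent scores mean "this engine
#' did not identify this spectrum".
#'
#' @return A list with character vectors `mandatory` and `optional` naming the
#'   columns of the dialect.
#' @export
psm_columns <- function() {
  list(
    mandatory = c("sample_id", "condition", "construct", "spectrum_id",
                  "peptide", "charge", "accessions"),
    optional  = c("mascot_ion_score", "sequest_xcorr", "sequest_deltacn",
                  "xtandem_neg_log_e", "peptide_probability", "mod_string")
  )
}

.conditions <- c("plus", "minus", "iM", "sM")
.constructs <- c("WT", "dPDZ", "none")
.aa_standard <- "ACDEFGHIKLMNPQRSTVWY"

#' Read and validate a PSM table
#'
#' Reads a tab-separated PSM report in the dialect of [psm_columns()]. Every
#' row is validated against the record invariants (condition/construct
#' vocabulary, peptide of >= 5 standard residues, integer charge >= 1, at
#' least one engine score, nonempty accession list, score ranges). Rows that
#' violate an invariant are rejected with a row-numbered diagnostic; no row is
#' silently dropped: `nrow(input) == nrow(accepted) + nrow(rejected)`.
#'
#' @param path Path to a TSV file with a header row.
#' @param quiet If `TRUE`, suppress the warning summarizing rejected rows.
#' @return A tibble of accepted PSMs in file order, with the rejected rows
#'   (columns `row` and `reason` plus the offending fields) available as
#'   `attr(x, "rejected")`.
#' @details A missing mandatory column and a duplicated
#'   `(sample_id, spectrum_id)` pair are structural errors and abort the read.
#' @export
read_psm_table <- function(path, quiet = FALSE) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("NA", ""))
  validate_psm_table(tibble::as_tibble(raw), quiet = quiet)
}

#' Validate an in-memory PSM table
#'
#' Same contract as [read_psm_table()] but starting from a data frame, so the
#' simulator output can be validated without a round-trip through disk.
#'
#' @param psms A data frame in the PSM dialect.
#' @param quiet If `TRUE`, no warning on rejected rows.
#' @return A tibble of accepted rows with a `rejected` attribute.
#' @export
validate_psm_table <- function(psms, quiet = FALSE) {
  cols <- psm_columns()
  missing_cols <- setdiff(cols$mandatory, names(psms))
  if (length(missing_cols) > 0) {
    stop("PSM table format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  psms <- tibble::as_tibble(psms)
  for (col in cols$optional) {
    if (!col %in% names(psms)) {
      psms[[col]] <- if (col == "mod_string") NA_character_ else NA_real_
    }
  }
  psms$construct <- as.character(psms$construct)
  psms$construct[is.na(psms$construct)] <- "none"
  psms$mod_string <- as.character(psms$mod_string)
  psms$peptide <- toupper(as.character(psms$peptide))
  psms$charge <- suppressWarnings(as.integer(psms$charge))
  for (col in setdiff(cols$optional, "mod_string")) {
    psms[[col]] <- suppressWarnings(as.numeric(psms[[col]]))
  }

  key <- paste(psms$sample_id, psms$spectrum_id, sep = "\r")
  if (anyDuplicated(key) > 0) {
    dup <- psms$spectrum_id[duplicated(key)][1]
    stop("PSM table duplication error: duplicate (sample_id, spectrum_id): ",
         dup, call. = FALSE)
  }

  reason <- rep(NA_character_, nrow(psms))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    reason[is.na(reason) & bad] <<- why
  }
  flag(!psms$condition %in% .conditions, "unknown condition")
  flag(!psms$construct %in% .constructs, "unknown construct")
  flag(is.na(psms$sample_id) | psms$sample_id == "", "empty sample_id")
  flag(is.na(psms$spectrum_id) | psms$spectrum_id == "", "empty spectrum_id")
  flag(nchar(psms$peptide) < 5, "peptide shorter than 5 residues")
  flag(grepl(sprintf("[^%s]", .aa_standard), psms$peptide),
       "peptide contains non-standard residues")
  flag(is.na(psms$charge) | psms$charge < 1, "charge must be an integer >= 1")
  flag(is.na(psms$accessions) | psms$accessions == "", "empty accession list")
  has_engine <- !is.na(psms$mascot_ion_score) |
    !is.na(psms$sequest_xcorr) | !is.na(psms$xtandem_neg_log_e)
  flag(!has_engine, "no engine score present")
  flag(!is.na(psms$mascot_ion_score) & psms$mascot_ion_score < 0,
       "negative mascot_ion_score")
  flag(!is.na(psms$sequest_xcorr) & psms$sequest_xcorr < 0,
       "negative sequest_xcorr")
  flag(!is.na(psms$sequest_deltacn) &
         (psms$sequest_deltacn < 0 | psms$sequest_deltacn > 1),
       "sequest_deltacn outside [0,1]")
  flag(!is.na(psms$peptide_probability) &
         (psms$peptide_probability < 0 | psms$peptide_probability > 1),
       "peptide_probability outside [0,1]")

  bad <- !is.na(reason)
  rejected <- psms[bad, , drop = FALSE]
  rejected$row <- which(bad)
  rejected$reason <- reason[bad]
  accepted <- psms[!bad, , drop = FALSE]
  accepted <- accepted[, c(cols$mandatory, cols$optional)]
  if (nrow(rejected) > 0 && !quiet) {
    warning(sprintf("rejected %d PSM row(s): %s", nrow(rejected),
                    paste(sprintf("row %d (%s)", rejected$row, rejected$reason),
                          collapse = "; ")),
            call. = FALSE)
  }
  attr(accepted, "rejected") <- rejected
  accepted
}

#' Write a PSM table
#'
#' Writes the dialect of [psm_columns()] with a fixed column order and tab
#' separation, so that `read_psm_table(write_psm_table(x))` round-trips
#' field-for-field.
#'
#' @param psms A PSM tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  cols <- psm_columns()
  keep <- intersect(c(cols$mandatory, cols$optional), names(psms))
  utils::write.table(psms[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Split semicolon-joined accession lists
#'
#' @param accessions Character vector of semicolon-joined accession tokens.
#' @return A list of character vectors.
#' @export
split_accessions <- function(accessions) {
  strsplit(as.character(accessions), ";", fixed = TRUE)
}

#' Read a protein sequence database from FASTA
#'
#' The accession is the first whitespace-delimited token of the header; the
#' remainder is kept as the description. Sequences are uppercased on read.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) {
    stop("FASTA format error: no records in ", path, call. = FALSE)
  }
  headers <- names(seqs)
  accession <- sub("\\s.*$", "", headers)
  description <- sub("^\\S+\\s*", "", headers)
  if (anyDuplicated(accession) > 0) {
    stop("FASTA format error: duplicated accession: ",
         accession[duplicated(accession)][1], call. = FALSE)
  }
  sequence <- toupper(as.character(seqs))
  if (any(nchar(sequence) == 0)) {
    stop("FASTA format error: sequence-less record: ",
         accession[nchar(sequence) == 0][1], call. = FALSE)
  }
  tibble::tibble(accession = accession, description = description,
                 sequence = unname(sequence))
}

#' Write a protein database to FASTA
#'
#' @param db Tibble as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line width for the sequence block.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path, width = 60L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(db))) {
    desc <- db$description[i]
    header <- if (is.na(desc) || desc == "") db$accession[i] else {
      paste(db$accession[i], desc)
    }
    writeLines(paste0(">", header), con)
    seq <- db$sequence[i]
    starts <- seq(1L, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1L, nchar(seq))),
               con)
  }
  invisible(path)
}

#' Read a domain-annotation table
#'
#' Tab-separated with columns `name`, `synonyms` (semicolon-joined, may be
#' empty), `is_pdz` (logical), `n_pdz_domains` (integer), `other_domains`
#' (semicolon-joined `domain:count` tokens). The invariant
#' `is_pdz == (n_pdz_domains >= 1)` is enforced.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble of annotations.
#' @export
read_annotation_table <- function(path) {
  stopifnot(file.exists(path))
  ann <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = "NA")
  need <- c("name", "is_pdz", "n_pdz_domains")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols) > 0) {
    stop("annotation table format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ann$is_pdz <- as.logical(ann$is_pdz)
  ann$n_pdz_domains <- as.integer(ann$n_pdz_domains)
  bad <- ann$is_pdz != (ann$n_pdz_domains >= 1)
  if (any(bad)) {
    stop("annotation invariant error: is_pdz inconsistent with ",
         "n_pdz_domains for: ", paste(ann$name[bad], collapse = ", "),
         call. = FALSE)
  }
  if (!"synonyms" %in% names(ann)) ann$synonyms <- NA_character_
  if (!"other_domains" %in% names(ann)) ann$other_domains <- NA_character_
  tibble::as_tibble(ann)
}

#' The packaged PDZ-protein reference table
#'
#' Loads the packaged reference of PDZ-domain proteins observed in the
#' pull-down screen (26 entries, `source == "pulldown"`) plus the extra PDZ
#' proteins encountered only in the membrane-fraction validation experiment
#' (`source == "validation"`). Domain inventories follow the SMART domain
#' nomenclature; `n_pdz_domains` counts PDZ repeats (e.g. MPDZ has 13,
#' INADL 10).
#'
#' @return A tibble of [read_annotation_table()] shape with a `source` column.
#' @export
pdz_reference <- function() {
  read_annotation_table(system.file("extdata", "pdz_reference.tsv",
                                    package = "apmsquant", mustWork = TRUE))
}

#' Printed membrane-fraction ratio table
#'
#' The published per-construct iM/sM nSC ratios of the ten PDZ proteins
#' quantified in the wild-type versus PDZ-motif-deleted validation experiment,
#' with statuses (`only_iM`, `only_sM`, `not_significant`) where a ratio is
#' undefined, and the printed one-decimal fold-enrichment column.
#'
#' @return A list of tibbles: `wt` and `dpdz` ratio maps in the shape consumed
#'   by [fold_enrichment()], and `printed` with the printed fold-enrichment
#'   strings.
#' @export
membrane_fraction_table <- function() {
  path <- system.file("extdata", "membrane_fraction_ratios.tsv",
                      package = "apmsquant", mustWork = TRUE)
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  parse_side <- function(x) {
    num <- suppressWarnings(as.numeric(x))
    tibble::tibble(
      name = raw$name,
      status = ifelse(is.na(num), x, "ratio"),
      ratio = num
    )
  }
  list(
    wt = parse_side(raw$ratio_wt),
    dpdz = parse_side(raw$ratio_dpdz),
    printed = tibble::tibble(name = raw$name, fe_printed = raw$fe_printed)
  )
}

#' Write a generic stage report
#'
#' Fixed column order, tab separation; numeric columns rendered with 4
#' significant digits except columns listed in `display_cols`, which are kept
#' verbatim (display-rounded strings). Infinite ratios are rendered `"inf"`.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param display_cols Character vector of columns written untouched.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, display_cols = character()) {
  out <- as.data.frame(x)
  for (col in names(out)) {
    if (is.list(out[[col]])) {
      out[[col]] <- vapply(out[[col]], function(v) {
        paste(as.character(v), collapse = ";")
      }, character(1))
    } else if (is.numeric(out[[col]]) && !col %in% display_cols) {
      v <- signif(out[[col]], 4)
      s <- as.character(v)
      s[is.infinite(v) & v > 0] <- "inf"
      s[is.infinite(v) & v < 0] <- "-inf"
      out[[col]] <- s
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
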