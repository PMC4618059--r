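#' Filter, infer and quantify one sample
#'
#' Convenience wrapper running the per-sample stages in order: peptide
#' filtering, peptide-to-protein mapping, parsimony grouping, protein
#' acceptance, and nSC computation.
#'
#' @param psms Validated PSM tibble for one sample.
#' @param criteria [filter_criteria()] for the peptide stage.
#' @param min_peptides,min_probability Protein acceptance rule.
#' @param db,remap Passed to [build_peptide_map()].
#' @param sample_id,condition Labels for the resulting quant; taken from the
#'   PSMs when omitted.
#' @return A `sample_quant` tibble (see [compute_nsc()]) with the accepted
#'   group table attached as `attr(x, "groups")` and the stage counts as
#'   `attr(x, "stage_counts")`.
#' @export
quantify_sample <- function(psms, criteria = filter_criteria(),
                            min_peptides = 2, min_probability = 0.99,
                            db = NULL, remap = FALSE,
                            sample_id = NULL, condition = NULL) {
  if (is.null(sample_id)) sample_id <- psms$sample_id[1]
  if (is.null(condition)) condition <- psms$condition[1]
  flt <- filter_psms(psms, criteria)
  map <- build_peptide_map(flt$accepted, db = db, remap = remap)
  groups <- group_by_parsimony(map, flt$accepted)
  accepted <- accept_proteins(
    groups, min_peptides = min_peptides, min_probability = min_probability,
    default_peptide_probability = criteria$peptide_probability_min
  )
  quant <- compute_nsc(accepted, sample_id = sample_id,
                       condition = condition)
  attr(quant, "groups") <- accepted
  attr(quant, "stage_counts") <- c(
    n_psms = nrow(psms), n_psms_accepted = nrow(flt$accepted),
    n_groups = nrow(groups), n_proteins_accepted = nrow(accepted)
  )
  quant
}

#' Pipeline configuration
#'
#' Builds the structured configuration consumed by [run_all()]. Either point
#' `psm_plus`/`psm_minus` (and optionally the four `fraction_*` paths) at PSM
#' TSV files, or set `simulate = TRUE` to run on synthetic data generated
#' from `sim` at `seed`.
#'
#' @param psm_plus,psm_minus Paths to the bait and control PSM tables.
#' @param fraction_paths Optional named list/vector with entries `wt_iM`,
#'   `wt_sM`, `dpdz_iM`, `dpdz_sM` pointing at the validation PSM tables.
#'   When `simulate = TRUE`, any non-`NULL` value requests simulation of the
#'   fractionation design as well.
#' @param simulate Generate inputs with the synthetic module instead of
#'   reading files.
#' @param sim A [synthetic_config()] used when `simulate = TRUE`.
#' @param annotation_path Annotation TSV; defaults to the packaged PDZ
#'   reference.
#' @param criteria Peptide [filter_criteria()].
#' @param min_peptides,min_probability Protein acceptance rule.
#' @param sc_min Default spectral-count significance cut-off.
#' @param sc_min_overrides Named per-sample overrides of `sc_min`.
#' @param ratio_min Hit rule for finite ratios (default `Inf`:
#'   bait-exclusive only).
#' @param fe_min Direct-binder fold-enrichment threshold.
#' @param seed Seed forwarded to the simulator.
#' @param outdir Optional output directory for reports, summary and log.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(psm_plus = NULL, psm_minus = NULL,
                            fraction_paths = NULL, simulate = FALSE,
                            sim = NULL, annotation_path = NULL,
                            criteria = filter_criteria(),
                            min_peptides = 2, min_probability = 0.99,
                            sc_min = 10, sc_min_overrides = list(),
                            ratio_min = Inf, fe_min = 2.0,
                            seed = 1L, outdir = NULL) {
  if (simulate && is.null(sim)) sim <- synthetic_config(seed = seed)
  structure(
    list(psm_plus = psm_plus, psm_minus = psm_minus,
         fraction_paths = fraction_paths, simulate = simulate, sim = sim,
         annotation_path = annotation_path, criteria = criteria,
         min_peptides = min_peptides, min_probability = min_probability,
         sc_min = sc_min, sc_min_overrides = sc_min_overrides,
         ratio_min = ratio_min, fe_min = fe_min,
         seed = as.integer(seed), outdir = outdir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `criteria` and `sim`
#' may be nested maps whose keys mirror [filter_criteria()] and
#' [synthetic_config()]. Unknown keys are an error, so typos do not pass
#' silently.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("config error: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$criteria)) {
    raw$criteria <- do.call(filter_criteria, raw$criteria)
  }
  if (!is.null(raw$sim)) raw$sim <- do.call(synthetic_config, raw$sim)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes filter, infer, quantify, enrichment calling and annotation on
#' the bait/control pair, and the fraction-validation stage when the four
#' fraction inputs are present; writes a machine-readable summary, the stage
#' reports and a log (including the documented deviations from the source
#' protocol's literal wording whenever the defaults are in use) when
#' `config$outdir` is set.
#'
#' @param config A [pipeline_config()] (or path to a YAML accepted by
#'   [read_pipeline_config()]).
#' @return A list with `summary` (stage counts, hit lists, PDZ partition,
#'   fold-enrichment table when computed), `enrichment`, `hitset`,
#'   `fold_enrichment`, `quants`, and `log` (character vector).
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(fmt, ...) {
    line <- if (...length() > 0) sprintf(fmt, ...) else fmt
    log <<- c(log, line)
  }
  note("apmsquant %s | seed %d | config hash %s",
       as.character(utils::packageVersion("apmsquant")), config$seed,
       rlang::hash(config[setdiff(names(config), "outdir")]))
  if (config$criteria$peptide_probability_min == 0.95) {
    note(paste("note: the source protocol's printed PeptideProphet cut-off",
               "('greater than 0.1%') is treated as a misprint; using",
               "probability >= 0.95"))
  }
  if (config$sc_min == 10) {
    note(paste("note: significance uses raw SC > 10 of the bait sample;",
               "the protocol's '(nSC > 10 to ∞)' parenthetical is read",
               "as SC (nSC cannot exceed 1)"))
  }

  annotations <- if (is.null(config$annotation_path)) {
    pdz_reference()
  } else {
    read_annotation_table(config$annotation_path)
  }

  fraction_tables <- NULL
  if (config$simulate) {
    note("simulate stage: generating pull-down pair (seed %d)", config$seed)
    sim <- simulate_pulldown(config$sim)
    psms_plus <- sim$plus
    psms_minus <- sim$minus
    if (!is.null(config$fraction_paths)) {
      note("simulate stage: generating fractionation quadruple")
      frac <- simulate_fractionation(config$sim, proteome = sim$proteome)
      fraction_tables <- frac$samples
    }
  } else {
    if (is.null(config$psm_plus) || !file.exists(config$psm_plus)) {
      stop("filter stage: bait ('+') PSM table missing: ",
           config$psm_plus %||% "<unset>", call. = FALSE)
    }
    if (is.null(config$psm_minus) || !file.exists(config$psm_minus)) {
      stop("quantify stage: resin-only ('-') control PSM table missing: ",
           config$psm_minus %||% "<unset>", call. = FALSE)
    }
    psms_plus <- read_psm_table(config$psm_plus, quiet = TRUE)
    psms_minus <- read_psm_table(config$psm_minus, quiet = TRUE)
    if (!is.null(config$fraction_paths)) {
      fp <- config$fraction_paths
      need <- c("wt_iM", "wt_sM", "dpdz_iM", "dpdz_sM")
      if (!all(need %in% names(fp))) {
        stop("validate stage: fraction_paths must name ",
             paste(need, collapse = ", "), call. = FALSE)
      }
      fraction_tables <- lapply(fp[need], function(p) {
        if (!file.exists(p)) {
          stop("validate stage: missing fraction PSM table: ", p,
               call. = FALSE)
        }
        read_psm_table(p, quiet = TRUE)
      })
    }
  }

  run_quant <- function(psms) {
    quantify_sample(psms, criteria = config$criteria,
                    min_peptides = config$min_peptides,
                    min_probability = config$min_probability)
  }
  quant_plus <- run_quant(psms_plus)
  quant_minus <- run_quant(psms_minus)
  counts_plus <- attr(quant_plus, "stage_counts")
  note("filter stage: '+' %d/%d PSMs accepted; '-' %d/%d",
       counts_plus[["n_psms_accepted"]], counts_plus[["n_psms"]],
       attr(quant_minus, "stage_counts")[["n_psms_accepted"]],
       attr(quant_minus, "stage_counts")[["n_psms"]])
  note("infer stage: %d protein groups accepted in '+'",
       counts_plus[["n_proteins_accepted"]])

  sc_min <- resolve_sc_min(attr(quant_plus, "sample_id") %||% "plus",
                           default = config$sc_min,
                           overrides = config$sc_min_overrides)
  enrichment <- call_enrichment(quant_plus, quant_minus, sc_min = sc_min,
                                ratio_min = config$ratio_min)
  note("quantify stage: %d hits at SC > %g", sum(enrichment$hit), sc_min)

  hitset <- annotate_hits(enrichment, annotations,
                          sample_id = attr(quant_plus, "sample_id"),
                          warn_unknown = FALSE)
  note("annotate stage: %d PDZ / %d non-PDZ hits",
       length(hitset$pdz_hits), length(hitset$nonpdz_hits))

  fe_records <- NULL
  binders <- NULL
  if (!is.null(fraction_tables)) {
    fq <- lapply(fraction_tables, run_quant)
    ratios_wt <- fraction_ratio(fq$wt_iM, fq$wt_sM, sc_min = config$sc_min)
    ratios_dpdz <- fraction_ratio(fq$dpdz_iM, fq$dpdz_sM,
                                  sc_min = config$sc_min)
    fe_records <- fold_enrichment(ratios_wt, ratios_dpdz)
    binders <- classify_direct_binders(fe_records, fe_min = config$fe_min)
    note("validate stage: %d direct binder(s) at FE > %g",
         length(binders), config$fe_min)
  }

  summary <- list(
    seed = config$seed,
    n_psms_plus = unname(counts_plus[["n_psms"]]),
    n_psms_accepted_plus = unname(counts_plus[["n_psms_accepted"]]),
    n_proteins_identified = unname(counts_plus[["n_proteins_accepted"]]),
    sc_min = sc_min,
    n_hits = sum(enrichment$hit),
    n_pdz_hits = length(hitset$pdz_hits),
    pdz_hits = hitset$pdz_hits,
    nonpdz_hits = hitset$nonpdz_hits,
    direct_binders = binders
  )
  if (!is.null(fe_records)) {
    summary$fold_enrichment <- fe_records[
      , c("name", "fold_enrichment", "display_fe")]
  }

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_enrichment_table(enrichment,
                           file.path(config$outdir, "enrichment.tsv"))
    if (!is.null(fe_records)) {
      write_fold_enrichment_table(fe_records,
                                  file.path(config$outdir,
                                            "fold_enrichment.tsv"))
    }
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log, file.path(config$outdir, "run.log"))
  }

  invisible(list(summary = summary, enrichment = enrichment,
                 hitset = hitset, fold_enrichment = fe_records,
                 quants = list(plus = quant_plus, minus = quant_minus),
                 log = log))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
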