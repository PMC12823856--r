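#' Assemble a pipeline configuration
#'
#' Validates and normalizes the configuration consumed by
#' [run_pipeline()]. `inputs` names the dialect files per database;
#' vocabulary and SMQ may be given as file paths or as objects. A YAML
#' file with the same structure can be loaded with [read_pipeline_config()].
#'
#' @param inputs Named list (names from [PV_DATABASES]); each element is a
#'   list with `paths` (as for [read_reports()]) and optionally `delim`.
#' @param vocabulary A [drug_vocabulary()] or CSV path.
#' @param smq An [smq_definition()] or term-list path.
#' @param indication_terms Cohort indication patterns.
#' @param signal_rule `"ANY"` or `"ALL"` (see [evaluate_signal()]).
#' @param continuity_correction Use the Yates chi-square for criterion 1.
#' @param age_threshold Age cut for the stratified analysis (years).
#' @param stratify_age Run the age-stratified analysis.
#' @param output_dir Directory for exported tables and the manifest
#'   (`NULL` = no files written).
#' @param seed Integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed also feeds any downstream resampling).
#' @param drugs Canonical drugs to tabulate (default: the vocabulary).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs, vocabulary = default_drug_vocabulary(),
                            smq = default_ild_smq(),
                            indication_terms = default_indication_terms(),
                            signal_rule = c("ANY", "ALL"),
                            continuity_correction = FALSE,
                            age_threshold = 65, stratify_age = TRUE,
                            output_dir = NULL, seed = 1L, drugs = NULL) {
  signal_rule <- match.arg(signal_rule)
  assert_that(is.list(inputs) && length(inputs) > 0 &&
                all(names(inputs) %in% PV_DATABASES),
              "inputs must be a list named by database dialect")
  for (dbn in names(inputs)) {
    paths <- unlist(inputs[[dbn]]$paths)
    assert_that(!is.null(paths), paste0(dbn, ": inputs need a 'paths' entry"))
    missing <- paths[!file.exists(paths)]
    assert_that(length(missing) == 0,
                paste0(dbn, ": input file(s) not found: ",
                       paste(missing, collapse = ", ")))
  }
  if (is.character(vocabulary)) vocabulary <- read_vocabulary(vocabulary)
  if (is.character(smq)) smq <- read_smq(smq)
  structure(
    list(inputs = inputs, vocabulary = vocabulary, smq = smq,
         indication_terms = indication_terms, signal_rule = signal_rule,
         continuity_correction = continuity_correction,
         age_threshold = age_threshold, stratify_age = stratify_age,
         output_dir = output_dir, seed = as.integer(seed),
         drugs = drugs %||% vocabulary_drugs(vocabulary)),
    class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()]; file paths in
#' it are resolved relative to the YAML file's directory.
#'
#' @param path Path to the YAML configuration.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(startsWith(p, "/"), p, file.path(base, p))
  inputs <- lapply(y$inputs, function(e) {
    e$paths <- lapply(e$paths, resolve)
    e
  })
  pipeline_config(
    inputs = inputs,
    vocabulary = if (!is.null(y$vocabulary)) resolve(y$vocabulary)
                 else default_drug_vocabulary(),
    smq = if (!is.null(y$smq)) resolve(y$smq) else default_ild_smq(),
    indication_terms = y$indication_terms %||% default_indication_terms(),
    signal_rule = y$signal_rule %||% "ANY",
    continuity_correction = isTRUE(y$continuity_correction),
    age_threshold = y$age_threshold %||% 65,
    stratify_age = !isFALSE(y$stratify_age),
    output_dir = if (!is.null(y$output_dir)) resolve(y$output_dir),
    seed = y$seed %||% 1L)
}

#' Run the full multi-database signal-detection pipeline
#'
#' Executes ingest, cohort filtering, study-drug restriction,
#' within-database deduplication and per-database signal tables; then
#' pools the databases, removes cross-database duplicates and computes
#' the combined signal table; finally runs the comparative analyses
#' (fatality, pairwise odds-ratio matrix, volcano statistics) per
#' universe and, optionally, the age-stratified signal tables. A manifest
#' records row counts at every stage (non-increasing through filters and
#' deduplication), the configuration echo, seed and package version.
#' Deterministic given inputs and seed. An empty cohort yields empty
#' tables with a warning, not an error.
#'
#' @param config A [pipeline_config()], or a YAML path accepted by
#'   [read_pipeline_config()].
#' @return An object of class `pv_pipeline_result`: list with
#'   `signal_tables` (named list of tibbles, per database plus
#'   `COMBINED`), `stratified` (per universe, when enabled), `fatality`,
#'   `pairwise`, `volcano`, `cohorts` (the deduplicated report sets),
#'   `manifest`, and `files` when `output_dir` was set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list()
  dbs <- names(config$inputs)

  cohorts <- list()
  for (dbn in dbs) {
    inp <- config$inputs[[dbn]]
    raw <- read_reports(inp$paths, dialect = dbn,
                        vocabulary = config$vocabulary,
                        delim = inp$delim %||% NULL)
    filt <- apply_cohort_filters(raw, config$indication_terms, config$smq)
    n_filt <- nrow(filt)
    study <- filt[filt$drug_mapped, ]
    dedup <- deduplicate(study, "WITHIN_DATABASE")
    stages[[dbn]] <- c(rows_read = nrow(raw), cohort_filtered = n_filt,
                       study_drug = nrow(study),
                       deduplicated = nrow(dedup))
    cohorts[[dbn]] <- dedup
  }

  pooled <- report_set(dplyr::bind_rows(cohorts),
                       provenance = unlist(lapply(cohorts, provenance)),
                       validate = FALSE)
  combined <- deduplicate(pooled, "CROSS_DATABASE")
  stages[["COMBINED"]] <- c(pooled = nrow(pooled),
                            deduplicated = nrow(combined))
  cohorts[["COMBINED"]] <- combined

  if (nrow(combined) == 0) {
    warning("empty cohort after filtering; emitting empty tables")
  }

  signal_tables <- list()
  fatality <- list()
  pairwise <- list()
  volcano <- list()
  stratified <- list()
  for (u in names(cohorts)) {
    x <- cohorts[[u]]
    label <- if (u == "COMBINED") "COMBINED" else u
    signal_tables[[u]] <- signal_table(
      x, drugs = config$drugs, universe_label = label,
      rule = config$signal_rule,
      continuity_correction = config$continuity_correction)
    if (nrow(x) > 0) {
      fatality[[u]] <- fatality_analysis(x)
      tab <- signal_tables[[u]]
      if (nrow(tab) >= 2) {
        pairwise[[u]] <- pairwise_ild_odds_matrix(tab)
        volcano[[u]] <- volcano_statistics(tab)
      }
      if (config$stratify_age) {
        stratified[[u]] <- stratified_signals(
          x, age_stratifier(config$age_threshold), drugs = config$drugs,
          rule = config$signal_rule,
          continuity_correction = config$continuity_correction)
      }
    }
  }

  manifest <- list(
    package_version = as.character(packageVersion("pvsignal")),
    seed = config$seed,
    stages = lapply(stages, as.list),  # named lists survive JSON round-trips
    universes = names(cohorts),
    drugs = config$drugs,
    signal_rule = config$signal_rule,
    continuity_correction = config$continuity_correction,
    age_threshold = config$age_threshold,
    indication_terms = config$indication_terms,
    smq = list(name = config$smq$name, scope = config$smq$scope,
               n_terms = length(config$smq$preferred_terms)),
    inputs = lapply(config$inputs, function(e) lapply(e$paths, basename)))

  result <- structure(
    list(signal_tables = signal_tables, stratified = stratified,
         fatality = fatality, pairwise = pairwise, volcano = volcano,
         cohorts = cohorts, manifest = manifest, files = NULL),
    class = "pv_pipeline_result")

  if (!is.null(config$output_dir)) {
    result$files <- export_tables(result, config$output_dir)
    manifest$files <- basename(unlist(result$files))
    result$manifest <- manifest
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.pv_pipeline_result <- function(x, ...) {
  cat("<pv_pipeline_result> universes:",
      paste(names(x$signal_tables), collapse = ", "), "\n")
  for (u in names(x$signal_tables)) {
    tab <- x$signal_tables[[u]]
    cat("  ", u, ": ", nrow(tab), " drugs, ", sum(tab$signal),
        " signal(s)\n", sep = "")
  }
  invisible(x)
}

#' Export pipeline results as delimited text
#'
#' Writes one TSV signal table per universe (full precision, mirroring
#' the per-universe layout of [signal_table()]), wide odds-ratio matrix
#' TSVs, volcano-coordinate TSVs (undefined-ROR drugs excluded, noted in
#' the return value), and fatality TSVs.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed; unwritable = error).
#' @param formats Currently `"tsv"`.
#' @return Named character vector of written file paths.
#' @export
export_tables <- function(result, dir, formats = "tsv") {
  stopifnot(inherits(result, "pv_pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(dir) && file.access(dir, 2) == 0,
              paste0("output directory not writable: ", dir))
  files <- character(0)
  w <- function(df, name) {
    path <- file.path(dir, name)
    readr::write_tsv(df, path)
    files[[name]] <<- path
    path
  }
  for (u in names(result$signal_tables)) {
    w(result$signal_tables[[u]], paste0("signal_", tolower(u), ".tsv"))
  }
  for (u in names(result$pairwise)) {
    pm <- result$pairwise[[u]]
    wide <- tibble::as_tibble(pm$or_matrix, rownames = "drug")
    w(wide, paste0("pairwise_or_", tolower(u), ".tsv"))
    w(pm$comparisons, paste0("pairwise_long_", tolower(u), ".tsv"))
  }
  for (u in names(result$volcano)) {
    v <- result$volcano[[u]]
    w(v[v$defined, ], paste0("volcano_", tolower(u), ".tsv"))
  }
  for (u in names(result$fatality)) {
    f <- result$fatality[[u]]
    if (!is.null(f$by_drug)) {
      w(f$by_drug, paste0("fatality_by_drug_", tolower(u), ".tsv"))
    }
    w(f$contrast, paste0("fatality_contrast_", tolower(u), ".tsv"))
  }
  files
}
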