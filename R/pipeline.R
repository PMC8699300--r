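#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> process -> variables -> compare and
#' writes a report bundle: the pattern table, exclusion summary, variable
#' matrix, comparison reports (one per contrast filter preset requested),
#' group summaries and a machine-readable run manifest with the seed and
#' read-count conservation at each stage.
#'
#' The configuration is a named list (or a JSON/YAML file holding one)
#' with exactly one of:
#'
#' * `simulate`: list with optional `reads_per_sample`, `seed`; the cohort
#'   is generated from [default_calibrated_model()] over the design;
#' * `inputs`: character vector of FASTQ paths.
#'
#' plus optional `design` (path to a design file; default the bundled
#' [demo_design()]), `min_conversion` (default 0.95), `filter` (report
#' preset, default `"none"`), `cv` (default `FALSE`), `mw` (`"exact"` or
#' `"screened"`, see [compare_all()]), `out_dir`.
#'
#' @param config named list or path to a JSON/YAML config file.
#' @return list (invisibly): `table`, `matrix`, `comparison`, `summary`,
#'   `manifest`, plus `truth` when simulating.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp) {
    abort_schema("config must contain exactly one of 'simulate' or 'inputs'")
  }
  design <- if (is.null(config$design)) demo_design() else
    load_design(config$design)
  min_conversion <- config$min_conversion %||% 0.95
  out_dir <- config$out_dir %||% tempfile("epialleler_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  seed <- NULL
  if (has_sim) {
    seed <- config$simulate$seed %||% 1L
    model <- default_calibrated_model(design)
    sim <- simulate_cohort(model, design,
                           dir = file.path(out_dir, "fastq"),
                           reads_per_sample = config$simulate$reads_per_sample,
                           seed = seed)
    files <- sim$files
    truth <- sim$truth
    n_input <- sum(sim$n_reads$n_reads)
  } else {
    files <- config$inputs
    n_input <- NA_integer_
  }

  table <- process_reads(files, design, min_conversion = min_conversion)
  excl <- exclusion_tallies(table)
  vm <- build_variable_matrix(table, design)
  cmp <- compare_all(vm, cv = isTRUE(config$cv),
                     mw = config$mw %||% "exact")
  preset <- config$filter %||% "none"
  report <- filter_report(cmp, preset)
  summ <- summarize_groups(vm)

  readr::write_tsv(as_tibble(table), file.path(out_dir, "pattern_table.tsv"))
  readr::write_tsv(excl, file.path(out_dir, "exclusions.tsv"))
  readr::write_tsv(as_tibble(vm), file.path(out_dir, "variable_matrix.tsv"))
  readr::write_tsv(report, file.path(out_dir, "comparison.tsv"))
  readr::write_tsv(summ$quartiles, file.path(out_dir, "group_quartiles.tsv"))
  readr::write_tsv(summ$correlations,
                   file.path(out_dir, "group_correlations.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("epialleler")),
    seed = seed,
    min_conversion = min_conversion,
    filter = preset,
    n_input_reads = n_input,
    n_retained = sum(table$count),
    n_excluded = sum(excl$n),
    n_samples = length(unique(vm$sample_id)),
    n_variables = length(variable_names(vm))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(table = table, matrix = vm, comparison = cmp,
                 summary = summ, manifest = manifest, truth = truth,
                 out_dir = out_dir))
}
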