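#' Default pipeline configuration
#'
#' Configuration for the end-to-end run: simulate (or ingest) a cohort,
#' screen variables with covariate adjustment, exhaustively search core sets,
#' compute grouped correlation matrices, and write ranked reports. All
#' randomness flows from one root seed through named per-stage substreams.
#'
#' @return A nested list understood by [run_gait_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    cohort = list(level = "table", n_stroke = 31, n_control = 41,
                  confounded = FALSE, table_csv = NULL),
    screening = list(alpha = 0.05, covariates = c("age", "sex", "bmi")),
    search = list(max_size = 4, threshold = 0.5, top_k = 5, constraint = NULL),
    correlations = list(groupings = c("pooled", "stroke", "control"),
                        variables = NULL)
  )
}

#' Validate a pipeline configuration
#'
#' Checks types and ranges of every recognised field and reports all
#' violations together with their field paths (e.g. `search.max_size`)
#' before any computation runs.
#'
#' @param config Nested list (or path of a YAML file).
#' @return The completed config (defaults filled in), invisibly on success;
#'   errors otherwise.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  assert_that(is.list(config), "config must be a list or a YAML file path.")
  def <- default_pipeline_config()
  config <- utils::modifyList(def, config)
  bad <- character()
  chk <- function(cond, path, msg) {
    if (!isTRUE(cond)) bad <<- c(bad, sprintf("%s: %s", path, msg))
  }
  chk(config$cohort$level %in% c("table", "curves"), "cohort.level",
      "must be \"table\" or \"curves\"")
  chk(is.null(config$cohort$table_csv) || is.character(config$cohort$table_csv),
      "cohort.table_csv", "must be a file path or null")
  chk(is_count(config$cohort$n_stroke) && config$cohort$n_stroke >= 2,
      "cohort.n_stroke", "must be an integer >= 2")
  chk(is_count(config$cohort$n_control) && config$cohort$n_control >= 2,
      "cohort.n_control", "must be an integer >= 2")
  chk(is.logical(config$cohort$confounded), "cohort.confounded", "must be logical")
  chk(is.numeric(config$screening$alpha) && config$screening$alpha > 0 &&
        config$screening$alpha < 1, "screening.alpha", "must be in (0, 1)")
  chk(is.character(config$screening$covariates), "screening.covariates",
      "must be a character vector")
  chk(is_count(config$search$max_size) && config$search$max_size >= 1,
      "search.max_size", "must be a positive integer")
  chk(is.numeric(config$search$threshold) && config$search$threshold > 0 &&
        config$search$threshold < 1, "search.threshold", "must be in (0, 1)")
  chk(is_count(config$search$top_k) && config$search$top_k >= 1,
      "search.top_k", "must be a positive integer")
  chk(is.null(config$search$constraint) || is.character(config$search$constraint),
      "search.constraint", "must be null or a character vector of variable names")
  chk(all(config$correlations$groupings %in% c("pooled", "stroke", "control")),
      "correlations.groupings", "must be among pooled/stroke/control")
  if (length(bad) > 0) {
    abort(paste0("invalid pipeline config:\n", paste0("  - ", bad, collapse = "\n")))
  }
  invisible(config)
}

#' Run the full core-set analysis pipeline
#'
#' Executes simulate (or ingest) -> (extract) -> screen -> search ->
#' correlate -> report, writing each stage's CSV output plus a JSON run
#' manifest into `out_dir`. Stage outputs already written are left intact if
#' a later stage fails. Re-running with the same config and seed reproduces
#' all outputs.
#'
#' @param config Nested list as [default_pipeline_config()], or a YAML path.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer root seed.
#' @return Invisibly, a list with the in-memory stage results (`table`,
#'   `screening`, `search`, `report`, `correlations`, `manifest`).
#' @export
run_gait_pipeline <- function(config = default_pipeline_config(), out_dir, seed) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf("[gaitcoreset %s] %s",
                                             format(Sys.time(), "%H:%M:%S"),
                                             sprintf(...)))

  # -- simulate / ingest ------------------------------------------------------
  if (!is.null(config$cohort$table_csv)) {
    log_stage("ingest: %s", config$cohort$table_csv)
    table <- read_cohort_csv(config$cohort$table_csv)
  } else if (config$cohort$level == "curves") {
    log_stage("simulate: curve-level cohort %d/%d", config$cohort$n_stroke,
              config$cohort$n_control)
    spec <- cohort_spec(n_stroke = config$cohort$n_stroke,
                        n_control = config$cohort$n_control,
                        confounded = config$cohort$confounded)
    cc <- simulate_curves(spec, seed = seed)
    reference <- fit_reference_bands(cc)
    log_stage("extract: %d subjects", nrow(cc$subjects))
    table <- extract_features(cc, reference)
  } else {
    log_stage("simulate: table-level cohort %d/%d", config$cohort$n_stroke,
              config$cohort$n_control)
    spec <- cohort_spec(n_stroke = config$cohort$n_stroke,
                        n_control = config$cohort$n_control,
                        confounded = config$cohort$confounded)
    table <- simulate_cohort(spec, seed = substream_seed(seed, "simulate"))
  }
  write_cohort_csv(table, file.path(out_dir, "cohort.csv"))

  # -- screen -----------------------------------------------------------------
  screening <- screen_all(table, covariates = config$screening$covariates,
                          alpha = config$screening$alpha)
  log_stage("screen: %d of %d variables included",
            sum(screening$included), nrow(screening))
  utils::write.csv(as.data.frame(screening), file.path(out_dir, "screening.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")

  # -- search -----------------------------------------------------------------
  candidates <- included_variables(screening)
  assert_that(length(candidates) >= 1, "no variables survived screening.")
  max_size <- min(config$search$max_size, length(candidates))
  search <- search_coresets(table, candidates, max_size = max_size,
                            threshold = config$search$threshold,
                            constraint = config$search$constraint,
                            top_k = config$search$top_k)
  log_stage("search: %d core sets scored, best MR %.3f",
            nrow(search$results), min(search$results$mr))
  rankings <- dplyr::select(search$results, "label", "size", "mr", "n_flagged_folds")
  utils::write.csv(rankings, file.path(out_dir, "coreset_rankings.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  report <- report_coresets(search)
  utils::write.csv(report, file.path(out_dir, "coreset_report.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")

  # -- correlate --------------------------------------------------------------
  corr_vars <- config$correlations$variables %||% candidates
  correlations <- lapply(config$correlations$groupings, function(g) {
    cm <- spearman_matrix(table, corr_vars, grouping = g)
    utils::write.csv(as.data.frame(cm),
                     file.path(out_dir, sprintf("correlations_%s.csv", g)),
                     row.names = FALSE, fileEncoding = "UTF-8")
    cm
  })
  names(correlations) <- config$correlations$groupings
  log_stage("correlate: %d groupings over %d variables",
            length(correlations), length(corr_vars))

  # -- manifest ---------------------------------------------------------------
  outputs <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package = "gaitcoreset",
    version = as.character(utils::packageVersion("gaitcoreset")),
    r_version = as.character(getRversion()),
    seed = seed,
    config = config,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(outputs, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))

  invisible(list(table = table, screening = screening, search = search,
                 report = report, correlations = correlations,
                 manifest = manifest))
}

#' Screening report in the included/excluded layout
#'
#' Formats a Step-I screen as the conventional variable-catalog table:
#' variables grouped by class (when a catalog with classes is supplied) and
#' partitioned into Included and Excluded.
#'
#' @param screening A `gait_screen`.
#' @param classes Optional tibble with `variable`, `class` columns.
#' @return A tibble: `partition`, `class`, `variable`, `estimate`, `p_value`.
#' @export
report_screening <- function(screening, classes = NULL) {
  out <- dplyr::transmute(
    tibble::as_tibble(screening),
    partition = ifelse(.data$included, "Included", "Excluded"),
    variable = .data$variable, estimate = .data$estimate, p_value = .data$p_value)
  if (!is.null(classes)) {
    out <- dplyr::left_join(out, dplyr::select(tibble::as_tibble(classes),
                                               "variable", "class"),
                            by = "variable")
    out <- dplyr::relocate(out, "partition", "class", "variable")
  }
  dplyr::arrange(out, dplyr::desc(.data$partition == "Included"), .data$variable)
}
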