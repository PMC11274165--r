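# pipeline entry points: thin orchestration over the modelling, link and
# statistics modules, suitable for calling from a shell wrapper; results
# go to files, diagnostics to messages (stderr), so outputs are pipeable

#' Simulate and export the coupled model
#'
#' Runs the compartmental simulation configured in `config`, attaches the
#' *Roseburia*-abundance and permeability time courses through the link
#' equations, and writes the combined trajectory to
#' `<out_dir>/trajectory.csv`.
#'
#' @param config A `run_config` from [read_run_config()].
#' @param out_dir Output directory, created if needed.
#' @return The trajectory file path, invisibly.
#' @export
cli_simulate <- function(config = default_run_config(), out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traj <- simulate_pkpd(config$pk, config$pd, config$schedule,
                        t_end = config$t_end, h = config$h)
  tc <- link_time_course(traj, config$cb_link, config$pm_link)
  path <- file.path(out_dir, "trajectory.csv")
  write_trajectory(traj, path, time_course = tc)
  message("trajectory written to ", path)
  invisible(path)
}

#' Analyse a cohort and export the statistical report
#'
#' Reads the cohort named by `config$analysis$cohort_path` (default: the
#' packaged observed cohort), runs [run_study_analysis()], and writes the
#' machine-readable report to `<out_dir>/report.json` together with a
#' human-readable `<out_dir>/report.txt`.
#'
#' @inheritParams cli_simulate
#' @return The JSON report path, invisibly.
#' @export
cli_analyze <- function(config = default_run_config(), out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- if (!is.null(config$analysis$cohort_path)) {
    read_cohort(config$analysis$cohort_path)
  } else {
    fixture_cohort()
  }
  report <- run_study_analysis(cohort)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(strip_classes(report), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt_path <- file.path(out_dir, "report.txt")
  con <- file(txt_path, "w")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print_study_report(report)
  message("report written to ", json_path)
  invisible(json_path)
}

#' Fit link equations from concentration-response pairs and export them
#'
#' Reads a comma-separated file with columns `c1_mg_per_ml`, `response`,
#' `response_kind` (given by `config$analysis$pairs_path`), fits each
#' response kind by [fit_link()], and writes the coefficients with their
#' r^2 to `<out_dir>/link_coefficients.json`.
#'
#' @inheritParams cli_simulate
#' @return The coefficients file path, invisibly.
#' @export
cli_fit_link <- function(config = default_run_config(), out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  path <- config$analysis$pairs_path
  if (is.null(path)) stop("config$analysis$pairs_path is required")
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("c1_mg_per_ml", "response", "response_kind")
  if (!all(need %in% names(d))) {
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- lapply(split(d, d$response_kind), function(g) {
    unclass(fit_link(g$c1_mg_per_ml, g$response, g$response_kind[1L]))
  })
  out <- file.path(out_dir, "link_coefficients.json")
  jsonlite::write_json(fits, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  message("coefficients written to ", out)
  invisible(out)
}

#' Generate a synthetic cohort and export it
#'
#' Draws a cohort from `config$synthetic` (see [cohort_spec()]) and
#' writes it to `<out_dir>/synthetic_cohort.csv` in the same long format
#' the analysis reads.
#'
#' @inheritParams cli_simulate
#' @param seed Optional integer overriding the spec seed.
#' @return The cohort file path, invisibly.
#' @export
cli_generate <- function(config = default_run_config(), out_dir = ".",
                         seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  spec <- config$synthetic
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "synthetic_cohort.csv")
  write_cohort(generate_cohort(spec), path)
  message("cohort written to ", path)
  invisible(path)
}

# recursively drop S3 classes so jsonlite serialises plain lists
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else {
    x
  }
}

print_study_report <- function(report) {
  cat("== Cohort summaries ==\n")
  for (ep in names(report$summaries)) {
    cat(sprintf("-- %s --\n", ep))
    for (ph in names(report$summaries[[ep]])) {
      s <- report$summaries[[ep]][[ph]]
      if (is.null(s)) next
      cat(sprintf("  %s: ", ph)); print(s)
    }
  }
  cat("\n== Paired t-tests (t0 vs t2) ==\n")
  for (ep in names(report$paired_tests)) {
    cat(sprintf("  %s: ", ep)); print(report$paired_tests[[ep]])
  }
  cat("\n== Activity-score vs RHI correlations ==\n")
  for (dis in names(report$correlations)) {
    cc <- report$correlations[[dis]]
    cat(sprintf("  %s (two-tailed): ", dis)); print(cc$two_tailed)
    cat(sprintf("  %s (one-tailed): ", dis)); print(cc$one_tailed)
  }
  invisible(report)
}
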