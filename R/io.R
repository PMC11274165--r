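# all tabular I/O is UTF-8 comma-separated text with a header row, '.'
# decimal separator, empty fields for missing values; floats carry 9
# significant digits so files round-trip losslessly at report precision

fmt9 <- function(x) {
  ifelse(is.na(x), "", formatC(x, digits = 9, format = "g"))
}

write_delim9 <- function(d, path) {
  out <- d
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- fmt9(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write cohort tables
#'
#' Cohorts are stored as comma-separated long-format text, one row per
#' patient and phase, with empty fields for missing endpoints; see
#' [validate_cohort()] for the column contract.
#'
#' @param path File path.
#' @param cohort Cohort data frame.
#' @return `read_cohort` returns the validated cohort data frame;
#'   `write_cohort` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  validate_cohort(d)
  d
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  write_delim9(cohort, path)
}

#' Read and write simulated trajectories
#'
#' Trajectories are stored with columns `time_day`, `C1_mg_per_L`,
#' `C2_mg_per_L`, `M_mg_per_L`, plus `Cb_rel_abundance` and
#' `Pm_cm2_per_s` when a link time course is attached.
#'
#' @param traj A `pkpd_trajectory`.
#' @param path File path.
#' @param time_course Optional data frame from [link_time_course()]
#'   computed on `traj`.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a data frame with the model-unit column names (`time`, `C1`,
#'   `C2`, `M`, and `Cb`/`Pm` when present).
#' @export
write_trajectory <- function(traj, path, time_course = NULL) {
  stopifnot(inherits(traj, "pkpd_trajectory"))
  out <- data.frame(time_day = traj$time, C1_mg_per_L = traj$C1,
                    C2_mg_per_L = traj$C2, M_mg_per_L = traj$M)
  if (!is.null(time_course)) {
    stopifnot(nrow(time_course) == nrow(traj))
    out$Cb_rel_abundance <- time_course$Cb
    out$Pm_cm2_per_s <- time_course$Pm
  }
  write_delim9(out, path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  map <- c(time_day = "time", C1_mg_per_L = "C1", C2_mg_per_L = "C2",
           M_mg_per_L = "M", Cb_rel_abundance = "Cb",
           Pm_cm2_per_s = "Pm")
  names(d) <- ifelse(names(d) %in% names(map), map[names(d)], names(d))
  d
}

#' Published per-phase endpoint summary statistics
#'
#' Returns the cohort-level summary tables for TEER (Ohm cm^2) and FD4
#' permeability (1e-6 cm^2/s): mean, median, sd, minimum and maximum at
#' phases t0/t1/t2 and for the healthy control group. Only these
#' summaries were published for the two endpoints (no per-patient raw
#' values), so they ship as data and cannot be re-derived by the
#' analysis functions.
#'
#' @return A data frame with columns `endpoint`, `unit`, `statistic`,
#'   `t0`, `t1`, `t2`, `control`.
#' @export
endpoint_summary_table <- function() {
  utils::read.csv(system.file("extdata", "endpoint_summaries.csv",
                              package = "vedopkpd", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Read a run configuration
#'
#' Loads a YAML run configuration with optional sections `model`
#' (pk/pd parameters, dosing schedule in weeks, `t_end_day`, `h_day`),
#' `link` (coefficient pairs), `synthetic` (cohort-spec fields) and
#' `analysis` (input paths, tails). Missing fields fall back to the
#' package defaults, which reproduce the clinical study configuration;
#' `default_run_config()` returns that baseline directly.
#'
#' @param path Path to a YAML file, or `NULL` for the packaged defaults.
#' @return A named list of class `run_config` with elements `pk`, `pd`,
#'   `schedule`, `t_end`, `h`, `cb_link`, `pm_link`, `synthetic`,
#'   `analysis`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  model <- cfg$model %||% list()
  pk <- do.call(pk_parameters, model$pk %||% list())
  pd <- do.call(pd_parameters, model$pd %||% list())
  sched_cfg <- model$schedule %||% list()
  schedule <- standard_schedule(
    pk,
    dose_mg = sched_cfg$dose_mg %||% 300,
    weeks = unlist(sched_cfg$weeks %||% c(0, 2, 6, seq(14, 52, by = 8))),
    first_increment = if (isTRUE(sched_cfg$first_dose_like_rest)) NULL
                      else sched_cfg$first_increment %||% 60)
  lk <- cfg$link %||% list()
  mk_link <- function(x, kind, default) {
    if (is.null(x)) default
    else link_coefficients(x$slope, x$intercept, kind)
  }
  syn <- cfg$synthetic %||% list()
  structure(list(
    pk = pk, pd = pd, schedule = schedule,
    t_end = model$t_end_day %||% 364,
    h = model$h_day %||% 0.01,
    cb_link = mk_link(lk$roseburia, "roseburia", roseburia_link()),
    pm_link = mk_link(lk$permeability, "permeability", permeability_link()),
    synthetic = do.call(cohort_spec, syn),
    analysis = cfg$analysis %||% list()
  ), class = "run_config")
}

#' @rdname read_run_config
#' @export
default_run_config <- function() read_run_config(NULL)

`%||%` <- function(a, b) if (is.null(a)) b else a
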