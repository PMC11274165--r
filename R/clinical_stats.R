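#' Validate a patient cohort table
#'
#' The cohort is a long-by-phase data frame with one row per patient and
#' phase. Required columns: `patient_id`, `disease` ("UC" or "CD"),
#' `therapy` ("naive" or "anti-TNF"), `phase` ("t0", "t1", "t2"),
#' `activity_score` (Partial Mayo Score for UC, Harvey-Bradshaw Index for
#' CD, integer >= 0) and `rhi` (Robarts Histopathological Index, integer
#' >= 0). Optional endpoint columns: `teer` (Ohm cm^2, > 0), `pm`
#' (cm^2/s, >= 0), `roseburia` (relative abundance in \[0, 1\]).
#'
#' @param cohort Data frame as described above.
#' @return The validated cohort, invisibly, with `phase` ordered
#'   t0 < t1 < t2.
#' @export
validate_cohort <- function(cohort) {
  need <- c("patient_id", "disease", "therapy", "phase",
            "activity_score", "rhi")
  if (!all(need %in% names(cohort))) {
    stop("missing columns: ", paste(setdiff(need, names(cohort)),
                                    collapse = ", "))
  }
  if (nrow(cohort) == 0L) stop("empty cohort")
  if (!all(cohort$disease %in% c("UC", "CD"))) {
    stop("'disease' must be 'UC' or 'CD'")
  }
  if (!all(cohort$phase %in% c("t0", "t1", "t2"))) {
    stop("'phase' must be one of 't0', 't1', 't2'")
  }
  for (nm in c("activity_score", "rhi")) {
    v <- cohort[[nm]]
    if (any(!is.na(v) & v < 0)) stop(sprintf("'%s' must be >= 0", nm))
  }
  if ("roseburia" %in% names(cohort)) {
    v <- cohort$roseburia
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("'roseburia' must lie in [0, 1]")
    }
  }
  per_pat <- split(cohort$phase, cohort$patient_id)
  if (any(vapply(per_pat, anyDuplicated, 0L) > 0L)) {
    stop("duplicated phase within a patient")
  }
  cohort$phase <- factor(cohort$phase, levels = c("t0", "t1", "t2"),
                         ordered = TRUE)
  invisible(cohort)
}

#' Cohort summary statistics
#'
#' Mean, median, standard deviation (n - 1 denominator), minimum and
#' maximum of a set of measurements, the layout used for the TEER and
#' permeability endpoint tables. A single observation yields sd = 0 with
#' `degenerate = TRUE`.
#'
#' @param values Numeric vector, non-empty after removing `NA`.
#' @return An object of class `cohort_summary`: a list with elements
#'   `mean`, `median`, `std`, `minimum`, `maximum`, `n`, `degenerate`.
#' @examples
#' summarize_cohort(c(17, 12, 6, 14, 12, 6, 23, 17, 23, 23, 19))
#' @export
summarize_cohort <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no non-missing values to summarise")
  degenerate <- length(values) == 1L
  structure(list(mean = mean(values),
                 median = stats::median(values),
                 std = if (degenerate) 0 else stats::sd(values),
                 minimum = min(values),
                 maximum = max(values),
                 n = length(values),
                 degenerate = degenerate),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("n = %d  mean = %.4g  median = %.4g  sd = %.4g  range = [%.4g, %.4g]\n",
              x$n, x$mean, x$median, x$std, x$minimum, x$maximum))
  invisible(x)
}

#' Paired-samples t-test
#'
#' Student's t-test on the paired differences d = x - y:
#' t = mean(d) / (sd(d)/sqrt(n)) with n - 1 degrees of freedom. With
#' `tails = "one"` the alternative is directional in the sense of the
#' observed mean difference, i.e. the reported p is half the two-sided p.
#'
#' @param x,y Equal-length numeric vectors, n >= 2.
#' @param tails `"two"` (default) or `"one"`.
#' @return An object of class `test_result`: a list with `statistic`,
#'   `df`, `p_value`, `tails`, `mean_difference`.
#' @examples
#' paired_t(c(17, 12, 6, 14), c(8, 6, 6, 1))
#' @export
paired_t <- function(x, y, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("all paired differences identical: degenerate test")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  p <- tt$p.value
  if (tails == "one") p <- p / 2
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = p,
                 tails = tails,
                 mean_difference = mean(d)),
            class = "test_result")
}

#' Pearson correlation with significance test
#'
#' Sample Pearson correlation r, tested via t = r sqrt(n-2)/sqrt(1-r^2)
#' with n - 2 degrees of freedom. With `tails = "one"` the alternative is
#' directional in the sense of the observed r (p is half the two-sided p).
#'
#' @param x,y Equal-length numeric vectors, n >= 3, each with nonzero
#'   variance.
#' @param tails `"two"` (default) or `"one"`.
#' @return A `test_result` list with additionally `r` and `n`.
#' @examples
#' pearson(1:10, (1:10) + rnorm(10))
#' @export
pearson <- function(x, y, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  p <- ct$p.value
  if (tails == "one") p <- p / 2
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = p,
                 tails = tails,
                 r = unname(ct$estimate),
                 n = length(x)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  if (!is.null(x$r)) {
    cat(sprintf("Pearson r = %.3f  (t = %.3f, df = %d, %s-tailed p = %.4g)\n",
                x$r, x$statistic, x$df, x$tails, x$p_value))
  } else {
    cat(sprintf("paired t = %.3f  (df = %d, %s-tailed p = %.4g)\n",
                x$statistic, x$df, x$tails, x$p_value))
  }
  invisible(x)
}

#' Run the full cohort statistical analysis
#'
#' One-pass orchestration of the study analyses: per-phase summaries of
#' each endpoint present (RHI, activity score, TEER, permeability,
#' *Roseburia* abundance), paired t-tests of t0 vs t2 for each endpoint,
#' and disease-stratified Pearson correlations between the clinical
#' activity score and RHI, pooling per-patient, per-phase pairs across
#' the three time points within each disease group (the pooling
#' convention that reproduces the published coefficients). Correlations
#' report both one- and two-tailed p-values. Endpoints with insufficient
#' data are skipped with a message, not an error.
#'
#' @param cohort Cohort data frame; see [validate_cohort()].
#' @param controls Optional data frame of control-group measurements with
#'   columns `patient_id` plus any of `teer`, `pm`, `roseburia`;
#'   summarised and compared (paired, in enrolment order) against the
#'   patients' t0 values where sizes match.
#' @return A `study_report` list with elements `summaries`,
#'   `paired_tests`, `correlations`, and `controls` (when given).
#' @examples
#' rep <- run_study_analysis(fixture_cohort())
#' rep$correlations$UC$two_tailed
#' @export
run_study_analysis <- function(cohort, controls = NULL) {
  cohort <- validate_cohort(cohort)
  endpoints <- intersect(c("rhi", "activity_score", "teer", "pm", "roseburia"),
                         names(cohort))

  summaries <- list()
  for (ep in endpoints) {
    if (all(is.na(cohort[[ep]]))) next
    summaries[[ep]] <- lapply(split(cohort[[ep]], cohort$phase),
                              function(v) {
                                if (all(is.na(v))) NULL else summarize_cohort(v)
                              })
  }

  paired_tests <- list()
  for (ep in endpoints) {
    wide <- phase_wide(cohort, ep)
    ok <- stats::complete.cases(wide[, c("t0", "t2")])
    if (sum(ok) < 2L) {
      message(sprintf("endpoint '%s': fewer than 2 complete t0/t2 pairs; skipped", ep))
      next
    }
    paired_tests[[ep]] <- tryCatch(
      paired_t(wide$t0[ok], wide$t2[ok]),
      error = function(e) {
        message(sprintf("endpoint '%s': %s", ep, conditionMessage(e)))
        NULL
      })
  }

  correlations <- list()
  for (dis in c("UC", "CD")) {
    sub <- cohort[cohort$disease == dis, , drop = FALSE]
    ok <- stats::complete.cases(sub[, c("activity_score", "rhi")])
    if (sum(ok) < 3L) next
    correlations[[dis]] <- list(
      two_tailed = pearson(sub$activity_score[ok], sub$rhi[ok], "two"),
      one_tailed = pearson(sub$activity_score[ok], sub$rhi[ok], "one"))
  }

  report <- list(summaries = summaries, paired_tests = paired_tests,
                 correlations = correlations)

  if (!is.null(controls)) {
    ctrl <- list()
    for (ep in intersect(c("teer", "pm", "roseburia"), names(controls))) {
      v <- controls[[ep]]
      if (all(is.na(v))) next
      ctrl[[ep]] <- list(summary = summarize_cohort(v))
      wide <- phase_wide(cohort, ep)
      if (sum(!is.na(wide$t0)) == sum(!is.na(v))) {
        ctrl[[ep]]$t0_vs_control <- tryCatch(
          paired_t(wide$t0[!is.na(wide$t0)], v[!is.na(v)]),
          error = function(e) NULL)
      }
    }
    report$controls <- ctrl
  }
  structure(report, class = "study_report")
}

# reshape one endpoint to patient x phase wide form
phase_wide <- function(cohort, endpoint) {
  out <- stats::reshape(
    cohort[, c("patient_id", "phase", endpoint)],
    idvar = "patient_id", timevar = "phase", direction = "wide")
  names(out) <- sub(paste0(endpoint, "."), "", names(out), fixed = TRUE)
  for (ph in c("t0", "t1", "t2")) {
    if (!ph %in% names(out)) out[[ph]] <- NA_real_
  }
  out[order(out$patient_id), ]
}
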