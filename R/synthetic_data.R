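#' Specification of a synthetic IBD cohort
#'
#' Defines the statistical structure of a generated cohort: per-phase
#' means and standard deviations for each endpoint, the UC/CD mix, and
#' the target pooled correlation between the clinical activity score and
#' the histological index. Defaults reproduce the observed 11-patient
#' cohort: activity-score and RHI moments from the per-patient tables,
#' TEER and FD4-permeability moments from the published phase summaries,
#' and *Roseburia* phase means implied by the fitted log-linear links at
#' the concentrations matching the permeability phase means.
#'
#' Each `*_means` / `*_stds` entry is a length-3 vector over phases
#' t0, t1, t2.
#'
#' @param n_patients Number of patients, >= 2.
#' @param uc_fraction Fraction of UC patients (remainder CD), in \[0, 1\].
#' @param pms_means,pms_stds Partial Mayo Score moments (UC patients).
#' @param hbi_means,hbi_stds Harvey-Bradshaw Index moments (CD patients).
#' @param rhi_means,rhi_stds Robarts Histopathological Index moments.
#' @param teer_means,teer_stds TEER moments, Ohm cm^2.
#' @param pm_means,pm_stds FD4 permeability moments, cm^2/s.
#' @param roseburia_means,roseburia_stds Relative-abundance moments.
#' @param target_score_rhi_correlation Target pooled Pearson correlation
#'   between activity score and RHI within each disease group, in
#'   \[-1, 1\].
#' @param seed Integer seed governing all draws.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 11,
                        uc_fraction = 7 / 11,
                        pms_means = c(7.857, 3.143, 2.857),
                        pms_stds = c(1.773, 1.574, 1.069),
                        hbi_means = c(7, 4, 2),
                        hbi_stds = c(2.160, 2.160, 1.826),
                        rhi_means = c(15.636, 6.636, 5.636),
                        rhi_stds = c(6.265, 4.178, 2.501),
                        teer_means = c(12.27, 18.12, 18.36),
                        teer_stds = c(3.15, 7.23, 4.86),
                        pm_means = c(0.883e-6, 0.814e-6, 0.735e-6),
                        pm_stds = c(0.451e-6, 0.446e-6, 0.552e-6),
                        roseburia_means = c(0.02661, 0.02768, 0.02891),
                        roseburia_stds = c(0.008, 0.008, 0.008),
                        target_score_rhi_correlation = 0.75,
                        seed = 42L) {
  if (n_patients < 2) stop("'n_patients' must be >= 2")
  if (uc_fraction < 0 || uc_fraction > 1) stop("'uc_fraction' in [0, 1]")
  if (abs(target_score_rhi_correlation) > 1) {
    stop("'target_score_rhi_correlation' must lie in [-1, 1]")
  }
  spec <- list(n_patients = as.integer(n_patients),
               uc_fraction = uc_fraction,
               pms_means = pms_means, pms_stds = pms_stds,
               hbi_means = hbi_means, hbi_stds = hbi_stds,
               rhi_means = rhi_means, rhi_stds = rhi_stds,
               teer_means = teer_means, teer_stds = teer_stds,
               pm_means = pm_means, pm_stds = pm_stds,
               roseburia_means = roseburia_means,
               roseburia_stds = roseburia_stds,
               target_score_rhi_correlation = target_score_rhi_correlation,
               seed = as.integer(seed))
  for (nm in grep("_stds$", names(spec), value = TRUE)) {
    v <- spec[[nm]]
    if (length(v) != 3L || any(v < 0)) {
      stop(sprintf("'%s' must be 3 non-negative values", nm))
    }
    if (length(spec[[sub("_stds$", "_means", nm)]]) != 3L) {
      stop("phase means must be length-3 vectors")
    }
  }
  structure(spec, class = "cohort_spec")
}

# within-phase Gaussian-copula correlation needed so that pooling the three
# phases (whose means co-trend) yields the target pooled correlation; the
# rounding/truncation bias of score discretisation is left uncorrected.
copula_rho <- function(mx, sdx, my, sdy, target) {
  pvar <- function(v) mean((v - mean(v))^2)
  pcov <- function(a, b) mean((a - mean(a)) * (b - mean(b)))
  if (mean(sdx * sdy) == 0) return(0) # noiseless scores: nothing to correlate
  vx <- mean(sdx^2) + pvar(mx)
  vy <- mean(sdy^2) + pvar(my)
  rho <- (target * sqrt(vx * vy) - pcov(mx, my)) / mean(sdx * sdy)
  if (!is.finite(rho) || abs(rho) > 1) {
    stop(sprintf(
      "target correlation %.3f infeasible after pooling (requires within-phase rho = %.3f)",
      target, rho))
  }
  rho
}

# underlying normal (mu, sigma) whose zero-truncated distribution has the
# requested mean and sd, so generated endpoints match the printed moments
# rather than inheriting an upward truncation bias; truncated moments are
# E = mu + sigma*lambda, V = sigma^2 (1 - lambda(lambda - alpha)) with
# alpha = -mu/sigma, lambda = phi(alpha)/(1 - Phi(alpha))
trunc_normal_params <- function(mean, sd) {
  if (sd == 0) return(c(mu = mean, sigma = 0))
  if (mean <= 0) stop("truncated-normal endpoint mean must be positive")
  if (mean / sd > 8) return(c(mu = mean, sigma = sd)) # truncation negligible
  obj <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    alpha <- -mu / sigma
    lambda <- stats::dnorm(alpha) / (1 - stats::pnorm(alpha))
    e <- mu + sigma * lambda
    v <- sigma^2 * (1 - lambda * (lambda - alpha))
    if (!is.finite(e) || !is.finite(v) || v <= 0) return(1e10)
    ((e - mean)^2 + (sqrt(v) - sd)^2) / sd^2
  }
  opt <- stats::optim(c(mean, log(sd)), obj,
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mu = opt$par[1], sigma = exp(opt$par[2]))
}

# draws from the zero-truncated normal with the given *truncated* moments,
# by rejection on the solved underlying normal
rtruncnorm0 <- function(n, par) {
  if (par[["sigma"]] == 0) return(rep(par[["mu"]], n))
  out <- stats::rnorm(n, par[["mu"]], par[["sigma"]])
  bad <- which(out < 0)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), par[["mu"]], par[["sigma"]])
    bad <- which(out < 0)
  }
  out
}

#' Generate a seeded synthetic patient cohort
#'
#' Draws a cohort with the structure of [cohort_spec()]: the first
#' `round(n * uc_fraction)` patients are UC, the rest CD; clinical
#' activity score and RHI are generated per phase from a bivariate
#' Gaussian copula (then rounded and floored at zero), with the
#' within-phase correlation chosen so that pooling the three phases
#' attains the target correlation in expectation; TEER, permeability and
#' *Roseburia* abundance are drawn from zero-truncated normals whose
#' underlying parameters are solved so that the truncated distribution has
#' the specified phase mean and sd. All draws derive from the single spec seed
#' through per-patient substreams indexed by patient number, so enlarging
#' the cohort leaves earlier patients unchanged.
#'
#' @param spec A `cohort_spec`.
#' @return A cohort data frame (long by phase) passing
#'   [validate_cohort()], with endpoint columns `teer`, `pm`,
#'   `roseburia` populated.
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 1))
#' head(cohort)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  n_uc <- round(n * spec$uc_fraction)
  rho_uc <- copula_rho(spec$pms_means, spec$pms_stds,
                       spec$rhi_means, spec$rhi_stds,
                       spec$target_score_rhi_correlation)
  rho_cd <- copula_rho(spec$hbi_means, spec$hbi_stds,
                       spec$rhi_means, spec$rhi_stds,
                       spec$target_score_rhi_correlation)

  trunc_par <- list()
  for (ep in c("teer", "pm", "roseburia")) {
    trunc_par[[ep]] <- lapply(1:3, function(j)
      trunc_normal_params(spec[[paste0(ep, "_means")]][j],
                          spec[[paste0(ep, "_stds")]][j]))
  }

  rows <- vector("list", n)
  phases <- c("t0", "t1", "t2")
  for (i in seq_len(n)) {
    set.seed((spec$seed %% 65011) * 32749L + 104729L + i)
    is_uc <- i <= n_uc
    if (is_uc) {
      mx <- spec$pms_means; sdx <- spec$pms_stds; rho <- rho_uc
    } else {
      mx <- spec$hbi_means; sdx <- spec$hbi_stds; rho <- rho_cd
    }
    z1 <- stats::rnorm(3)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(3)
    score <- pmax(0, round(mx + sdx * z1))
    rhi <- pmax(0, round(spec$rhi_means + spec$rhi_stds * z2))
    teer <- vapply(1:3, function(j) rtruncnorm0(1L, trunc_par$teer[[j]]), 0)
    pm <- vapply(1:3, function(j) rtruncnorm0(1L, trunc_par$pm[[j]]), 0)
    ros <- vapply(1:3, function(j)
      rtruncnorm0(1L, trunc_par$roseburia[[j]]), 0)
    rows[[i]] <- data.frame(
      patient_id = i,
      disease = if (is_uc) "UC" else "CD",
      therapy = if (stats::runif(1) < 0.5) "naive" else "anti-TNF",
      phase = phases,
      activity_score = score,
      rhi = rhi,
      teer = teer,
      pm = pm,
      roseburia = pmin(1, ros),
      stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, rows)
  validate_cohort(cohort)
  cohort
}

#' The observed 11-patient IBD cohort
#'
#' Returns the pilot-study cohort exactly as published: 11 patients
#' (7 UC, 4 CD, mixed naive/anti-TNF history) with their clinical
#' activity scores (PMS for UC, HBI for CD) and Robarts Histopathological
#' Index at phases t0 (pre-treatment), t1 (24 weeks) and t2 (52 weeks).
#' TEER, permeability and *Roseburia* columns are `NA`: only summary
#' statistics of those endpoints were published, not per-patient values.
#'
#' @return A cohort data frame of 33 rows (11 patients x 3 phases).
#' @examples
#' fixture_cohort()
#' @export
fixture_cohort <- function() {
  path <- system.file("extdata", "ibd_cohort_scores.csv",
                      package = "vedopkpd", mustWork = TRUE)
  cohort <- read_cohort(path)
  cohort$teer <- NA_real_
  cohort$pm <- NA_real_
  cohort$roseburia <- NA_real_
  cohort
}
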