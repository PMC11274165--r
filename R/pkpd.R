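#' Pharmacokinetic parameters of the two blood compartments
#'
#' Constructs and validates the parameter set of the linear two-compartment
#' disposition model for intravenous Vedolizumab: drug exchanges between a
#' central and a peripheral blood compartment at flow rate `Qb` and is
#' eliminated from the peripheral compartment by first-order kinetics.
#'
#' Defaults are the values adopted for the three-compartment model of the
#' IBD cohort study. Time is measured in days throughout, so `K` is a
#' day^-1 rate (half-life ln(2)/K ~ 18.8 days, consistent with the
#' 14--21 day terminal half-lives reported for the antibody) and `Qb` is
#' in L/day.
#'
#' @param Qb Inter-compartment blood flow rate, L/day.
#' @param V1 Central blood compartment volume, L.
#' @param V2 Peripheral blood compartment volume, L.
#' @param K First-order elimination rate constant, day^-1.
#' @return An object of class `pk_parameters`.
#' @examples
#' pk_parameters()
#' pk_parameters(K = 0.05)
#' @export
pk_parameters <- function(Qb = 0.12, V1 = 3.12, V2 = 1.65, K = 0.0368) {
  for (nm in c("Qb", "V1", "V2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive finite number", nm))
    }
  }
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K < 0) {
    stop("'K' must be a single non-negative finite number")
  }
  structure(list(Qb = Qb, V1 = V1, V2 = V2, K = K), class = "pk_parameters")
}

#' Pharmacodynamic parameters of MAdCAM-1 suppression
#'
#' Parameters of the Hill (Emax) relationship between peripheral-blood drug
#' concentration and the effective intestinal concentration of the
#' endothelial adhesion molecule MAdCAM-1; see [madcam()].
#'
#' @param M0 Baseline MAdCAM-1 concentration with no drug, mg/L.
#' @param Emax Maximum fractional suppression, dimensionless in \[0, 1\].
#' @param gamma Hill coefficient, dimensionless, > 0.
#' @param E50 Peripheral drug concentration at half-maximum effect, mg/L.
#' @return An object of class `pd_parameters`.
#' @examples
#' pd_parameters()
#' @export
pd_parameters <- function(M0 = 2.23e-2, Emax = 0.956, gamma = 0.3512,
                          E50 = 0.093) {
  if (!is.numeric(M0) || length(M0) != 1L || !is.finite(M0) || M0 <= 0) {
    stop("'M0' must be a single positive number")
  }
  if (!is.numeric(Emax) || length(Emax) != 1L || Emax < 0 || Emax > 1) {
    stop("'Emax' must lie in [0, 1]")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("'gamma' must be positive")
  }
  if (!is.numeric(E50) || length(E50) != 1L || E50 <= 0) {
    stop("'E50' must be positive")
  }
  structure(list(M0 = M0, Emax = Emax, gamma = gamma, E50 = E50),
            class = "pd_parameters")
}

#' Instantaneous IV dose events
#'
#' A dose event adds a concentration increment to the central compartment
#' at a given time; an IV bolus of `dose_mg` milligrams corresponds to an
#' increment of `dose_mg / V1` mg/L.
#'
#' @param time_day Event times, days, >= 0.
#' @param increment Concentration increments added to C1, mg/L, >= 0.
#' @return A `dose_events` data frame sorted by time.
#' @seealso [standard_schedule()] for the clinical induction/maintenance
#'   regimen.
#' @export
dose_events <- function(time_day, increment) {
  if (length(time_day) != length(increment)) {
    stop("'time_day' and 'increment' must have equal length")
  }
  if (any(!is.finite(time_day)) || any(time_day < 0)) {
    stop("dose times must be finite and >= 0")
  }
  if (any(!is.finite(increment)) || any(increment < 0)) {
    stop("dose increments must be finite and >= 0")
  }
  ord <- order(time_day)
  structure(data.frame(time_day = time_day[ord], increment = increment[ord]),
            class = c("dose_events", "data.frame"))
}

#' Clinical Vedolizumab dosing schedule
#'
#' Builds the dose-event table for the standard regimen: 300 mg IV at weeks
#' 0, 2 and 6 (induction), then every 8 weeks (maintenance) up to week 52.
#' Weeks are converted to days as 1 week = 7 days.
#'
#' By default the first event is a direct 60 mg/L increment, the initial
#' central concentration used by the model; set `first_increment = NULL`
#' to treat the first dose like the rest (300/V1 ~ 96 mg/L).
#'
#' @param pk `pk_parameters`; supplies V1 for the mg -> mg/L conversion.
#' @param dose_mg IV bolus dose, mg.
#' @param weeks Dosing weeks.
#' @param first_increment Direct C1 increment (mg/L) for the first event, or
#'   `NULL` to use `dose_mg / V1` for all events.
#' @return A `dose_events` data frame.
#' @examples
#' standard_schedule(pk_parameters())
#' @export
standard_schedule <- function(pk = pk_parameters(), dose_mg = 300,
                              weeks = c(0, 2, 6, seq(14, 52, by = 8)),
                              first_increment = 60) {
  stopifnot(inherits(pk, "pk_parameters"))
  inc <- rep(dose_mg / pk$V1, length(weeks))
  if (!is.null(first_increment)) inc[1L] <- first_increment
  dose_events(time_day = weeks * 7, increment = inc)
}

#' MAdCAM-1 concentration under drug suppression
#'
#' Hill (Emax) model of the effective intestinal MAdCAM-1 concentration as
#' a function of the peripheral-blood drug concentration:
#' \deqn{M = M_0 \left(1 - \frac{E_{max} \, C_2^{\gamma}}{E_{50}^{\gamma} +
#'   C_2^{\gamma}}\right)}
#' It is monotone non-increasing in `c2`, equals `M0` at zero drug and
#' approaches `M0 * (1 - Emax)` at saturating concentrations.
#'
#' @param c2 Peripheral-blood drug concentration(s), mg/L, >= 0.
#' @param pd `pd_parameters`.
#' @return MAdCAM-1 concentration(s), mg/L, same length as `c2`.
#' @examples
#' madcam(0, pd_parameters())       # baseline M0
#' madcam(0.093, pd_parameters())   # half-maximum suppression
#' @export
madcam <- function(c2, pd = pd_parameters()) {
  stopifnot(inherits(pd, "pd_parameters"))
  if (any(!is.finite(c2)) || any(c2 < 0)) {
    stop("'c2' must be finite and >= 0")
  }
  frac <- ifelse(c2 == 0, 0,
                 c2^pd$gamma / (pd$E50^pd$gamma + c2^pd$gamma))
  pd$M0 * (1 - pd$Emax * frac)
}

#' Simulate the three-compartment Vedolizumab model
#'
#' Integrates the linear two-compartment disposition system
#' \deqn{dC_1/dt = (Q_b/V_1)(C_2 - C_1)}
#' \deqn{dC_2/dt = (Q_b/V_2)(C_1 - C_2) - K C_2}
#' by the explicit Euler method on a uniform grid, applying each dose event
#' as an instantaneous jump in C1 at the nearest grid point not after the
#' event time, and evaluates the intestinal MAdCAM-1 concentration
#' pointwise from C2 via [madcam()]. Initial conditions are C1 = C2 = 0
#' before events; a dose at t = 0 establishes C1(0) (the clinical default
#' is 60 mg/L with C2(0) = 0).
#'
#' @param pk `pk_parameters`.
#' @param pd `pd_parameters`.
#' @param schedule `dose_events`; all times must be <= `t_end`.
#' @param t_end End of the simulation, days, > 0.
#' @param h Euler step, days, > 0. The 0.01-day default keeps the
#'   first-order discretisation error orders of magnitude below clinical
#'   data resolution.
#' @return A `pkpd_trajectory` data frame with columns `time` (day),
#'   `C1`, `C2`, `M` (mg/L) and the parameter sets stored as attributes.
#' @examples
#' traj <- simulate_pkpd(t_end = 52 * 7)
#' head(traj)
#' @export
simulate_pkpd <- function(pk = pk_parameters(), pd = pd_parameters(),
                          schedule = standard_schedule(pk),
                          t_end = 364, h = 0.01) {
  stopifnot(inherits(pk, "pk_parameters"), inherits(pd, "pd_parameters"),
            inherits(schedule, "dose_events"))
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("'h' must be a single positive number")
  }
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0) {
    stop("'t_end' must be a single positive number")
  }
  if (nrow(schedule) && any(schedule$time_day > t_end)) {
    stop("dose events must not occur after 't_end'")
  }

  times <- seq(0, t_end, by = h)
  n <- length(times)
  C1 <- numeric(n)
  C2 <- numeric(n)

  # map each event to the last grid index with grid time <= event time
  # (tiny tolerance so an event at an exact grid time lands on it)
  ev_idx <- pmin(floor(schedule$time_day / h + 1e-9) + 1L, n)
  jumps <- numeric(n)
  for (j in seq_along(ev_idx)) {
    jumps[ev_idx[j]] <- jumps[ev_idx[j]] + schedule$increment[j]
  }

  a <- pk$Qb / pk$V1
  b <- pk$Qb / pk$V2
  C1[1L] <- jumps[1L]
  for (i in seq_len(n - 1L)) {
    C1[i + 1L] <- C1[i] + h * a * (C2[i] - C1[i]) + jumps[i + 1L]
    C2[i + 1L] <- C2[i] + h * (b * (C1[i] - C2[i]) - pk$K * C2[i])
  }

  out <- data.frame(time = times, C1 = C1, C2 = C2, M = madcam(C2, pd))
  structure(out, class = c("pkpd_trajectory", "data.frame"),
            pk = pk, pd = pd, h = h)
}

#' Closed-form solution of the two-compartment system
#'
#' Exact solution of the linear 2x2 ODE system of the disposition model for
#' a single initial central concentration `c1_0` and C2(0) = 0, by
#' eigen-decomposition of the system matrix (with the Jordan limiting form
#' when the eigenvalues coincide). Serves as an independent oracle for the
#' Euler integrator.
#'
#' @param pk `pk_parameters`.
#' @param c1_0 Initial central concentration, mg/L.
#' @param t Evaluation time(s), days, >= 0.
#' @return A data frame with columns `time`, `C1`, `C2`.
#' @examples
#' closed_form_two_compartment(pk_parameters(), 60, c(0, 14, 42))
#' @export
closed_form_two_compartment <- function(pk, c1_0, t) {
  stopifnot(inherits(pk, "pk_parameters"))
  if (any(t < 0)) stop("'t' must be >= 0")
  a <- pk$Qb / pk$V1
  b <- pk$Qb / pk$V2
  # system matrix A = [[-a, a], [b, -(b+K)]]
  tr <- -a - b - pk$K
  det <- a * (b + pk$K) - a * b # = a*K
  disc <- tr^2 - 4 * det
  x0 <- c(c1_0, 0)

  if (disc > 1e-12 * max(tr^2, 1)) {
    s <- sqrt(disc)
    l1 <- (tr + s) / 2
    l2 <- (tr - s) / 2
    # eigenvectors: (A - l I) v = 0 -> v = (a, l + a)
    V <- cbind(c(a, l1 + a), c(a, l2 + a))
    coef <- solve(V, x0)
    C1 <- coef[1] * V[1, 1] * exp(l1 * t) + coef[2] * V[1, 2] * exp(l2 * t)
    C2 <- coef[1] * V[2, 1] * exp(l1 * t) + coef[2] * V[2, 2] * exp(l2 * t)
  } else {
    # repeated eigenvalue: exp(At) = e^(lt) (I + (A - lI) t)
    l <- tr / 2
    N11 <- -a - l
    N12 <- a
    N21 <- b
    N22 <- -(b + pk$K) - l
    C1 <- exp(l * t) * (x0[1] + t * (N11 * x0[1] + N12 * x0[2]))
    C2 <- exp(l * t) * (x0[2] + t * (N21 * x0[1] + N22 * x0[2]))
  }
  data.frame(time = t, C1 = C1, C2 = C2)
}

#' Estimate the elimination rate constant from concentration data
#'
#' Least-squares fit of the first-order elimination constant K to observed
#' central-compartment concentrations following a single IV bolus, with the
#' remaining disposition parameters held fixed. The objective is the sum of
#' squared deviations between the observations and the closed-form model
#' prediction, minimised over K by golden-section search.
#'
#' @param times Observation times, days.
#' @param c1_obs Observed central concentrations, mg/L.
#' @param pk `pk_parameters` supplying Qb, V1, V2 (its K is ignored).
#' @param c1_0 Initial central concentration, mg/L.
#' @param interval Search interval for K, day^-1.
#' @return A list with `K` (the estimate) and `objective` (residual sum of
#'   squares).
#' @export
fit_elimination <- function(times, c1_obs, pk = pk_parameters(), c1_0 = 60,
                            interval = c(1e-4, 1)) {
  stopifnot(length(times) == length(c1_obs), length(times) >= 3)
  sse <- function(K) {
    pkK <- pk_parameters(Qb = pk$Qb, V1 = pk$V1, V2 = pk$V2, K = K)
    pred <- closed_form_two_compartment(pkK, c1_0, times)$C1
    sum((pred - c1_obs)^2)
  }
  opt <- stats::optimize(sse, interval = interval)
  list(K = opt$minimum, objective = opt$objective)
}
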