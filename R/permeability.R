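#' Ussing-chamber FD4 flux measurement
#'
#' Holds the raw quantities of a 4 kDa FITC-dextran (FD4) paracellular flux
#' measurement in an Ussing chamber, from which the apparent intestinal
#' permeability is computed by [compute_pm()]. Geometry defaults are those
#' of the biopsy mounting used in the clinical study: exchange surface
#' 0.017 cm^2, initial donor concentration 1e4 pmol/cm^3 (1 mg/mL FD4),
#' membrane thickness 2.175e-3 cm.
#'
#' @param Qt FD4 amount transported at time `t`, pmol, >= 0.
#' @param t Elapsed time, s, > 0.
#' @param S Exchange surface area, cm^2, > 0.
#' @param C0 Initial donor FD4 concentration, pmol/cm^3, > 0.
#' @param delta_m Membrane thickness, cm, > 0.
#' @return A `ussing_measurement` data frame (vectorised over `Qt`, `t`).
#' @export
ussing_measurement <- function(Qt, t, S = 0.017, C0 = 1e4,
                               delta_m = 2.175e-3) {
  d <- data.frame(Qt = Qt, t = t, S = S, C0 = C0, delta_m = delta_m)
  if (any(!is.finite(d$Qt)) || any(d$Qt < 0)) stop("'Qt' must be >= 0")
  for (nm in c("t", "S", "C0", "delta_m")) {
    if (any(!is.finite(d[[nm]])) || any(d[[nm]] <= 0)) {
      stop(sprintf("'%s' must be strictly positive", nm))
    }
  }
  structure(d, class = c("ussing_measurement", "data.frame"))
}

#' Apparent intestinal permeability from FD4 flux
#'
#' Computes the apparent permeability of the intestinal biopsy to the FD4
#' probe as
#' \deqn{P_m = \frac{Q_t \, \delta_m}{S \, t \, C_0}}
#' with units pmol * cm / (cm^2 * s * pmol/cm^3) = cm^2/s.
#'
#' @param m A `ussing_measurement`.
#' @return Apparent permeability value(s), cm^2/s.
#' @examples
#' compute_pm(ussing_measurement(Qt = 1000, t = 3600))
#' @export
compute_pm <- function(m) {
  stopifnot(inherits(m, "ussing_measurement"))
  m$Qt * m$delta_m / (m$S * m$t * m$C0)
}

#' Scale permeability values for reporting
#'
#' Clinical summaries report FD4 permeability in units of 1e-6 cm^2/s;
#' this formatter applies the corresponding scaling.
#'
#' @param pm Permeability value(s), cm^2/s.
#' @return The same values expressed in 1e-6 cm^2/s.
#' @export
format_pm <- function(pm) pm * 1e6

#' Read raw Ussing-chamber measurements from delimited text
#'
#' Expects a comma-separated file with header columns `patient_id`,
#' `phase`, `Qt_pmol`, `t_s`; chamber geometry constants are supplied
#' separately (they are fixed per apparatus, not per record).
#'
#' @param path File path.
#' @param S,C0,delta_m Geometry constants, as in [ussing_measurement()].
#' @return A data frame with the input columns plus `pm` (cm^2/s).
#' @export
read_ussing <- function(path, S = 0.017, C0 = 1e4, delta_m = 2.175e-3) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "phase", "Qt_pmol", "t_s")
  if (!all(need %in% names(d))) {
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  }
  m <- ussing_measurement(Qt = d$Qt_pmol, t = d$t_s, S = S, C0 = C0,
                          delta_m = delta_m)
  d$pm <- compute_pm(m)
  d
}
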