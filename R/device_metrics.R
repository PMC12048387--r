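# ---- Device characterization: tensile, toughness, power, sensitivity ----

#' Engineering stress-strain curve
#'
#' @param strain engineering strain (dimensionless), non-decreasing.
#' @param stress engineering stress (MPa), same length.
#' @return object of class \code{stress_strain_curve}; the failure strain is
#'   the last strain value.
#' @export
stress_strain_curve <- function(strain, stress) {
  if (length(strain) != length(stress)) stop("strain and stress lengths differ")
  if (length(strain) < 1) stop("empty curve")
  if (is.unsorted(strain)) stop("strain must be non-decreasing")
  structure(list(strain = as.numeric(strain), stress = as.numeric(stress),
                 failure_strain = strain[length(strain)]),
            class = "stress_strain_curve")
}

#' Tensile modulus from the initial linear range
#'
#' Least-squares slope of stress against strain restricted to the window
#' within \code{fraction} (default 20\%) of the maximum strain; on an exact
#' line this equals the point ratio stress/strain.
#'
#' @param curve a \code{\link{stress_strain_curve}}.
#' @param fraction linear-range fraction of the maximum strain, default 0.2.
#' @return modulus (MPa).
#' @examples
#' tensile_modulus(stress_strain_curve(c(0, 0.1, 0.2, 1), c(0, 0.2, 0.4, 2)))
#' @export
tensile_modulus <- function(curve, fraction = 0.2) {
  stopifnot(inherits(curve, "stress_strain_curve"), fraction > 0)
  sel <- curve$strain <= fraction * max(curve$strain)
  if (sum(sel) < 2)
    stop("fewer than two points within the linear range")
  unname(stats::coef(stats::lm(curve$stress[sel] ~ curve$strain[sel]))[2])
}

#' Toughness: area under the stress-strain curve
#'
#' Trapezoidal integral of engineering stress over strain up to failure.
#' With stress in MPa and dimensionless strain the result is in MJ/m^3
#' (identically J/cm^3).
#'
#' @param curve a \code{\link{stress_strain_curve}}.
#' @return toughness (MJ/m^3).
#' @export
toughness <- function(curve) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  pracma::trapz(curve$strain, curve$stress)
}

#' Areal power density across a load resistor
#'
#' \eqn{P = V^2 / (A R)}.
#'
#' @param voltage measured voltage (V).
#' @param resistance load resistance (ohm), > 0.
#' @param area device contact area (m^2), > 0.
#' @return power density (W/m^2).
#' @examples
#' power_density(2, 1e6, 4e-4)  # 0.01 W/m^2
#' @export
power_density <- function(voltage, resistance, area) {
  if (!(resistance > 0)) stop("resistance must be positive")
  if (!(area > 0)) stop("area must be positive")
  voltage^2 / (area * resistance)
}

#' Force-to-voltage sensitivity fit
#'
#' Least-squares linear fit (with intercept) of peak voltage against peak
#' force.
#'
#' @param force peak forces (N).
#' @param voltage peak voltages (V), same length.
#' @return list: \code{slope} (V/N), \code{se} (its standard error),
#'   \code{intercept}, and the underlying \code{lm} fit.
#' @examples
#' estimate_sensitivity(c(2, 4, 6), c(1, 2, 3))$slope  # 0.5
#' @export
estimate_sensitivity <- function(force, voltage) {
  if (length(force) != length(voltage)) stop("force and voltage lengths differ")
  if (length(force) < 2) stop("at least two points required")
  if (max(force) - min(force) <= 0) stop("force values have no spread")
  fit <- stats::lm(voltage ~ force)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["force", "Estimate"]),
       se = unname(sm["force", "Std. Error"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       fit = fit)
}

#' Per-cycle peak voltages of a cyclic compression test
#'
#' Splits the trace into cycles at the punch period and returns the maximum
#' voltage of each cycle.
#'
#' @param wave a \code{\link{waveform}} from
#'   \code{\link{simulate_standard_test}} (or a measured trace).
#' @param freq punch frequency (Hz).
#' @return numeric vector of per-cycle peaks (V).
#' @export
cycle_peaks <- function(wave, freq) {
  stopifnot(inherits(wave, "waveform"), freq > 0)
  n_cyc <- floor(length(wave$samples) * freq / wave$fs)
  per <- wave$fs / freq
  vapply(seq_len(n_cyc), function(c0) {
    idx <- floor((c0 - 1) * per) + seq_len(floor(per))
    max(wave$samples[idx[idx <= length(wave$samples)]])
  }, numeric(1))
}
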