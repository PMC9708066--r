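# Sharpe-Schoolfield thermal performance curve: evaluation and derived
# quantities (peak rate, operational niche width, Arrhenius correction).

#' Boltzmann constant in eV per Kelvin
#'
#' @format Length-one numeric, 8.617e-5 eV K^-1.
#' @export
boltzmann_k <- 8.617e-5

.CELSIUS0 <- 273.15

#' Celsius/Kelvin conversion helpers
#'
#' @param x temperature(s) in degrees Celsius (`celsius_to_kelvin`) or
#'   Kelvin (`kelvin_to_celsius`).
#' @return numeric vector of converted temperatures.
#' @export
celsius_to_kelvin <- function(x) x + .CELSIUS0

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x) x - .CELSIUS0

#' Construct a Sharpe-Schoolfield parameter set
#'
#' Bundles the four curve parameters plus the fixed reference temperature
#' into a validated object.  `B0` is the rate at the reference temperature
#' `Tref` (in the absence of high-temperature deactivation), `E` the
#' activation energy (eV) governing the rise of the curve, `ED` the
#' deactivation energy (eV) governing the fall beyond the peak, and `Tpk`
#' the temperature (K) at which the rate peaks.  `ED > E` is required for
#' `Tpk` to be a true maximum.
#'
#' @param B0 rate at `Tref`; must be > 0.
#' @param E activation energy in eV; must be > 0.
#' @param ED deactivation energy in eV; must exceed `E`.
#' @param Tpk peak temperature in Kelvin; must be > 0.
#' @param Tref reference temperature in Kelvin (fixed, not fitted).
#'   `Tref` only rescales `B0`; it never affects `Tpk`, `E` or `ED`.
#' @return an object of class `"ss_params"`: a named list with the five
#'   elements above.
#' @examples
#' p <- ss_params(B0 = 1, E = 0.65, ED = 3, Tpk = 300)
#' ss_evaluate(p, 290:310)
#' @export
ss_params <- function(B0, E, ED, Tpk, Tref = 273.15) {
  stopifnot(is.numeric(B0), is.numeric(E), is.numeric(ED), is.numeric(Tpk))
  if (!is.finite(B0) || B0 <= 0) stop("B0 must be positive and finite")
  if (!is.finite(E) || E <= 0) stop("E must be positive and finite")
  if (!is.finite(ED) || ED <= E) stop("ED must exceed E")
  if (!is.finite(Tpk) || Tpk <= 0) stop("Tpk must be positive (Kelvin)")
  if (!is.finite(Tref) || Tref <= 0) stop("Tref must be positive (Kelvin)")
  structure(list(B0 = B0, E = E, ED = ED, Tpk = Tpk, Tref = Tref),
            class = "ss_params")
}

#' @export
print.ss_params <- function(x, digits = 4, ...) {
  cat("Sharpe-Schoolfield parameters:\n")
  cat(sprintf("  B0  = %.*g (rate at Tref = %.2f K)\n", digits, x$B0, x$Tref))
  cat(sprintf("  E   = %.*g eV\n", digits, x$E))
  cat(sprintf("  ED  = %.*g eV\n", digits, x$ED))
  cat(sprintf("  Tpk = %.*g K (%.2f degC)\n", digits, x$Tpk,
              kelvin_to_celsius(x$Tpk)))
  invisible(x)
}

#' Evaluate the Sharpe-Schoolfield model
#'
#' Computes the biological rate at absolute temperature `temp` under the
#' four-parameter Sharpe-Schoolfield model with explicit peak temperature:
#' \deqn{B(T) = \frac{B_0 e^{-\frac{E}{k}(1/T - 1/T_{ref})}}
#'   {1 + \frac{E}{E_D - E} e^{\frac{E_D}{k}(1/T_{pk} - 1/T)}}}
#' where \eqn{k} is the Boltzmann constant (8.617e-5 eV/K).  The rate is
#' strictly positive and, for valid parameters, maximized exactly at
#' `Tpk`.
#'
#' @param params an [ss_params] object (or a list with the same fields).
#' @param temp temperature(s) in Kelvin; must be > 0.
#' @return numeric vector of rates, same length as `temp`.
#' @export
ss_evaluate <- function(params, temp) {
  if (!is.numeric(temp) || any(!is.finite(temp)) || any(temp <= 0))
    stop("temp must be positive finite Kelvin temperatures")
  if (params$ED <= params$E) stop("ED must exceed E")
  k <- boltzmann_k
  rise <- params$B0 * exp(-params$E / k * (1 / temp - 1 / params$Tref))
  fall <- 1 + params$E / (params$ED - params$E) *
    exp(params$ED / k * (1 / params$Tpk - 1 / temp))
  rise / fall
}

#' Peak rate of a Sharpe-Schoolfield curve
#'
#' Closed-form evaluation of the curve at its peak `T = Tpk`:
#' `B0 * exp(-E/k * (1/Tpk - 1/Tref)) / (1 + E/(ED - E))`.
#'
#' @inheritParams ss_evaluate
#' @return the peak rate (same units as `B0`).
#' @export
peak_rate <- function(params) {
  if (params$ED <= params$E) stop("ED must exceed E")
  k <- boltzmann_k
  params$B0 * exp(-params$E / k * (1 / params$Tpk - 1 / params$Tref)) /
    (1 + params$E / (params$ED - params$E))
}

#' Operational niche width
#'
#' The difference between the thermal optimum and the temperature below it
#' at which the rate falls to 50% of its maximum, i.e.
#' `Topt - T_half` with `B(T_half) = 0.5 * peak_rate(params)` and
#' `T_half < Tpk`.  A generalist/specialist index: wide curves give large
#' values.  The half-maximum crossing is located by bracketed root finding
#' ([stats::uniroot]) between `floor` and the peak.  If the curve is still
#' above half-maximum at `floor` (very shallow rise), the width is
#' undefined and `NA` is returned with attribute `defined = FALSE`.
#'
#' @inheritParams ss_evaluate
#' @param floor lower search bound in degrees Celsius (default -10).
#'   Must lie below the peak temperature.
#' @param tol convergence tolerance passed to [stats::uniroot], in Kelvin.
#' @return niche width in degrees C (a difference, so identical in K),
#'   or `NA` (attribute `defined = FALSE`) when the curve never drops to
#'   half-maximum above `floor`.
#' @export
operational_niche_width <- function(params, floor = -10, tol = 1e-9) {
  floor_k <- celsius_to_kelvin(floor)
  if (floor_k >= params$Tpk) stop("floor must lie below the peak temperature")
  bmax <- peak_rate(params)
  f <- function(tk) ss_evaluate(params, tk) - 0.5 * bmax
  if (f(floor_k) > 0) {
    return(structure(NA_real_, defined = FALSE))
  }
  root <- stats::uniroot(f, lower = floor_k, upper = params$Tpk, tol = tol)
  structure(params$Tpk - root$root, defined = TRUE)
}

#' Arrhenius temperature correction of a rate
#'
#' Rescales a rate observed at `t_obs` to the value expected at `t_target`
#' assuming Boltzmann-Arrhenius temperature dependence with activation
#' energy `E`: `rate * exp(E/k * (1/T_obs - 1/T_target))` with
#' temperatures in Kelvin.  Used to standardize rates measured at
#' different temperatures (e.g. to 20 degC with E = 0.61 eV) before
#' cross-taxon comparison.
#'
#' @param rate observed rate(s); must be positive.
#' @param t_obs observation temperature(s), degrees Celsius.
#' @param t_target target temperature, degrees Celsius.
#' @param E activation energy in eV (default 0.61).
#' @return corrected rate(s).
#' @export
arrhenius_correct <- function(rate, t_obs, t_target = 20, E = 0.61) {
  if (!is.numeric(rate) || any(!is.finite(rate)) || any(rate <= 0))
    stop("rate must be positive and finite")
  to <- celsius_to_kelvin(t_obs)
  tt <- celsius_to_kelvin(t_target)
  rate * exp(E / boltzmann_k * (1 / to - 1 / tt))
}
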