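# Derivation of physiological traits from raw growth-respiration-ATP
# assay measurements.

# fgC per cell as a function of cell volume (um^3): a = coefficient,
# b = allometric exponent (< 1, so the relation is concave).
.CARBON_A <- 133.754
.CARBON_B <- 0.438

# ATP luminescence calibration: log10(nM ATP) = ATP_SLOPE*log10(RLU) + ATP_INT
.ATP_SLOPE <- 1.21
.ATP_INT <- -4.69

#' Sphere volume from diameter
#'
#' Cells are treated as spheres, so volume = pi * d^3 / 6.  Supply
#' measured volumes directly to downstream functions to override the
#' shape assumption.
#'
#' @param diameter cell diameter(s) in micrometres; must be >= 0.
#' @return volume(s) in cubic micrometres.
#' @export
sphere_volume <- function(diameter) {
  if (any(!is.finite(diameter)) || any(diameter < 0))
    stop("diameter must be non-negative and finite")
  pi * diameter^3 / 6
}

#' Carbon content per cell from cell volume
#'
#' Allometric volume-to-carbon relation `fgC = 133.754 * V^0.438`
#' (V in cubic micrometres), an empirical calibration for bacterial
#' cells.  Monotone increasing and concave in V.
#'
#' @param volume cell volume(s) in cubic micrometres; must be >= 0.
#' @return carbon mass per cell in femtograms.
#' @export
carbon_per_cell <- function(volume) {
  if (any(!is.finite(volume)) || any(volume < 0))
    stop("volume must be non-negative and finite")
  .CARBON_A * volume^.CARBON_B
}

#' Carbon biomass of a culture
#'
#' Cell count times per-cell carbon content at the mean cell volume.
#'
#' @param count cell count (cells per assay volume); must be >= 0.
#' @param mean_volume mean cell volume in cubic micrometres.
#' @return biomass in fgC (per the same assay volume).
#' @export
culture_biomass <- function(count, mean_volume) {
  if (any(!is.finite(count)) || any(count < 0))
    stop("count must be non-negative and finite")
  count * carbon_per_cell(mean_volume)
}

#' Mass-specific exponential growth rate
#'
#' Assuming exponential growth from initial biomass `C0` to final biomass
#' `Ctot` over `t` hours, `mu = log(Ctot / C0) / t` (natural log).
#' Negative when the culture shrank.
#'
#' @param C0 initial biomass; must be > 0.
#' @param Ctot final biomass; must be > 0.
#' @param t assay duration in hours; must be > 0.
#' @return growth rate in per hour.
#' @export
growth_rate <- function(C0, Ctot, t) {
  if (any(!is.finite(C0)) || any(C0 <= 0)) stop("C0 must be positive")
  if (any(!is.finite(Ctot)) || any(Ctot <= 0)) stop("Ctot must be positive")
  if (any(!is.finite(t)) || any(t <= 0)) stop("t must be positive")
  log(Ctot / C0) / t
}

#' Biomass-specific respiration rate of a growing culture
#'
#' Converts cumulative respired carbon `Rtot` into a biomass-specific
#' rate while accounting for the exponential change in biomass over the
#' assay: `R = mu * Rtot / (C0 * exp(mu * t) - C0)`.  As `mu -> 0` the
#' denominator vanishes with `mu`; for `|mu * t|` below `eps` the
#' analytic limit `Rtot / (C0 * t)` is used for numerical stability.
#' Negative `mu` (shrinking cultures) is allowed and handled by the same
#' expression.
#'
#' @param mu growth rate in per hour (any finite value).
#' @param Rtot cumulative respired carbon over the assay, same mass unit
#'   as `C0`; must be >= 0.
#' @param C0 initial biomass; must be > 0.
#' @param t assay duration in hours; must be > 0.
#' @param eps threshold on `|mu * t|` below which the zero-growth limit
#'   is used.
#' @return respiration rate in per hour (mass C respired per mass C
#'   biomass per hour).
#' @export
respiration_rate <- function(mu, Rtot, C0, t, eps = 1e-8) {
  if (any(!is.finite(mu))) stop("mu must be finite")
  if (any(!is.finite(Rtot)) || any(Rtot < 0)) stop("Rtot must be >= 0")
  if (any(!is.finite(C0)) || any(C0 <= 0)) stop("C0 must be positive")
  if (any(!is.finite(t)) || any(t <= 0)) stop("t must be positive")
  out <- ifelse(abs(mu * t) < eps,
                Rtot / (C0 * t),
                mu * Rtot / (C0 * exp(mu * t) - C0))
  out
}

#' ATP concentration from a luminescence time series
#'
#' The luminescence reaction develops over a few minutes; the highest
#' relative-light-unit (RLU) reading across timepoints is taken and
#' converted via the calibration curve
#' `log10(nM ATP) = 1.21 * log10(RLU) - 4.69`.
#'
#' @param rlu_series numeric vector of RLU readings (one per timepoint),
#'   or a two-column matrix/data.frame of (minutes, RLU); all RLU must
#'   be > 0.
#' @return ATP concentration in nM.
#' @export
atp_concentration <- function(rlu_series) {
  rlu <- if (is.matrix(rlu_series) || is.data.frame(rlu_series)) {
    as.numeric(as.data.frame(rlu_series)[[min(2, ncol(rlu_series))]])
  } else {
    as.numeric(rlu_series)
  }
  if (length(rlu) == 0) stop("rlu_series must be non-empty")
  if (any(!is.finite(rlu)) || any(rlu <= 0))
    stop("all RLU readings must be positive and finite")
  peak <- max(rlu)
  10^(.ATP_SLOPE * log10(peak) + .ATP_INT)
}

#' ATP content normalized by biomass
#'
#' @param atp ATP concentration in nM; must be >= 0.
#' @param biomass culture carbon biomass (fgC scale); must be > 0.
#' @return nM ATP per biomass unit.  Downstream analyses use its
#'   natural log.
#' @export
atp_per_biomass <- function(atp, biomass) {
  if (any(!is.finite(atp)) || any(atp < 0)) stop("atp must be >= 0")
  if (any(!is.finite(biomass)) || any(biomass <= 0))
    stop("biomass must be positive")
  atp / biomass
}

#' Derive all physiological traits from one assay record
#'
#' Runs the full derivation chain on one replicate's raw measurements:
#' mean cell volume (spheres from diameters), per-cell carbon, initial
#' and final culture biomass, mass-specific growth rate, biomass-specific
#' respiration rate, and (when a luminescence series is present) ATP
#' concentration and ATP per biomass.
#'
#' @param record a list or one-row data.frame with elements
#'   `isolate_id`, `assay_temp` (degC), `t` (h), `initial_count`,
#'   `final_count`, `diameters` (um; scalar mean or vector),
#'   `Rtot` (fgC), and optionally `rlu_series` (see
#'   [atp_concentration]) and `od600`.
#' @return a one-row data.frame of class `"derived_traits"` with columns
#'   `isolate_id`, `assay_temp`, `mean_cell_volume`, `C0`, `Ctot`, `mu`,
#'   `R`, `atp`, `atp_per_biomass`.
#' @seealso [generate_assay_batch] for the synthetic inverse.
#' @export
derive_traits <- function(record) {
  d <- record$diameters
  if (is.list(d)) d <- unlist(d)
  vol <- mean(sphere_volume(d))
  C0 <- culture_biomass(record$initial_count, vol)
  Ctot <- culture_biomass(record$final_count, vol)
  mu <- growth_rate(C0, Ctot, record$t)
  R <- respiration_rate(mu, record$Rtot, C0, record$t)
  rlu <- record$rlu_series
  if (is.list(rlu) && length(rlu) == 1) rlu <- rlu[[1]]
  atp <- if (is.null(rlu)) NA_real_ else atp_concentration(rlu)
  out <- data.frame(
    isolate_id = as.character(record$isolate_id),
    assay_temp = as.numeric(record$assay_temp),
    mean_cell_volume = vol,
    C0 = C0, Ctot = Ctot, mu = mu, R = R,
    atp = atp,
    atp_per_biomass = if (is.na(atp)) NA_real_ else atp_per_biomass(atp, C0),
    stringsAsFactors = FALSE
  )
  class(out) <- c("derived_traits", class(out))
  out
}

#' Derive traits for every row of an assay table
#'
#' @param table a data.frame of assay records, one row per replicate,
#'   with columns as in [derive_traits]; RLU readings may be supplied as
#'   wide columns `rlu_t0`, `rlu_t2`, `rlu_t4`, `rlu_t6`.
#' @return a data.frame with one derived-trait row per input row.
#' @export
derive_traits_table <- function(table) {
  rlu_cols <- grep("^rlu_t", names(table), value = TRUE)
  rows <- lapply(seq_len(nrow(table)), function(i) {
    rec <- as.list(table[i, , drop = FALSE])
    if (length(rlu_cols))
      rec$rlu_series <- as.numeric(table[i, rlu_cols])
    derive_traits(rec)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
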