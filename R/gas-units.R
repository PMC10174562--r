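#' Seawater gas conditions
#'
#' Bundle the temperature, salinity and barometric pressure context that every
#' oxygen unit conversion in the package depends on. All conversions between
#' percent air saturation, oxygen partial pressure (PO2, mm Hg) and dissolved
#' oxygen concentration (DO, mg O2 L^-1) are defined relative to
#' air-equilibrated water under these conditions.
#'
#' @param temperature Water temperature, degrees Celsius. Must lie in
#'   \[0, 40\].
#' @param salinity Practical salinity (ppt). Must lie in \[0, 40\].
#' @param pressure Barometric pressure. Interpreted according to
#'   `pressure_unit`; stored internally in mm Hg. Must resolve to
#'   \[500, 800\] mm Hg.
#' @param pressure_unit Either `"mmHg"` (default) or `"hPa"`. hPa input is
#'   converted by the factor 0.750062 mm Hg per hPa on ingest.
#' @param o2_mole_fraction Mole fraction of oxygen in dry air
#'   (default 0.2095).
#'
#' @return An object of class `gas_conditions`: a list with elements
#'   `temperature`, `salinity`, `barometric_pressure` (mm Hg) and
#'   `o2_mole_fraction`.
#' @examples
#' gas_conditions(28, 33, 758)
#' gas_conditions(28, 33, 1011, pressure_unit = "hPa")
#' @export
gas_conditions <- function(temperature = 28, salinity = 33, pressure = 758,
                           pressure_unit = c("mmHg", "hPa"),
                           o2_mole_fraction = 0.2095) {
  pressure_unit <- match.arg(pressure_unit)
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.numeric(salinity), length(salinity) == 1L,
            is.numeric(pressure), length(pressure) == 1L)
  p_mmhg <- if (pressure_unit == "hPa") pressure * 0.750062 else pressure
  if (temperature < 0 || temperature > 40)
    stop("temperature must be in [0, 40] degrees C, got ", temperature)
  if (salinity < 0 || salinity > 40)
    stop("salinity must be in [0, 40] ppt, got ", salinity)
  if (p_mmhg < 500 || p_mmhg > 800)
    stop("barometric pressure must be in [500, 800] mm Hg, got ",
         format(p_mmhg))
  if (o2_mole_fraction <= 0 || o2_mole_fraction >= 1)
    stop("o2_mole_fraction must be in (0, 1)")
  structure(list(temperature = temperature, salinity = salinity,
                 barometric_pressure = p_mmhg,
                 o2_mole_fraction = o2_mole_fraction),
            class = "gas_conditions")
}

#' @export
print.gas_conditions <- function(x, ...) {
  cat(sprintf(
    "Gas conditions: T = %g degC, S = %g ppt, P = %g mm Hg, xO2 = %g\n",
    x$temperature, x$salinity, x$barometric_pressure, x$o2_mole_fraction))
  invisible(x)
}

as_gas_conditions <- function(cond) {
  if (inherits(cond, "gas_conditions")) return(cond)
  stop("expected a 'gas_conditions' object; see gas_conditions()")
}

#' Saturation vapor pressure of water
#'
#' Antoine equation with coefficients valid over 0--100 degrees C
#' (A = 8.07131, B = 1730.63, C = 233.426; pressure in mm Hg). Used to remove
#' the water-vapor contribution from barometric pressure when computing the
#' partial pressure of oxygen in air-equilibrated water.
#'
#' @param temperature Degrees Celsius, in \[0, 100\]. Vectorised.
#' @return Saturation vapor pressure in mm Hg; strictly increasing in
#'   temperature.
#' @examples
#' water_vapor_pressure(28)  # ~28.3 mm Hg
#' water_vapor_pressure(100) # ~760 mm Hg
#' @export
water_vapor_pressure <- function(temperature) {
  if (any(!is.finite(temperature)) ||
      any(temperature < 0 | temperature > 100))
    stop("temperature must be in [0, 100] degrees C")
  10^(8.07131 - 1730.63 / (233.426 + temperature))
}

#' Oxygen partial pressure of air-equilibrated water
#'
#' PO2 at 100% air saturation: `(P_baro - p_H2O(T)) * x_O2`, i.e. the dry-gas
#' fraction of barometric pressure times the oxygen mole fraction. For the
#' conditions of a tropical reef system (28 degC, 758 mm Hg) this is
#' approximately 152.9 mm Hg.
#'
#' @param cond A [gas_conditions()] object.
#' @return PO2 in mm Hg.
#' @examples
#' po2_at_full_air_saturation(gas_conditions(28, 33, 758))
#' @export
po2_at_full_air_saturation <- function(cond) {
  cond <- as_gas_conditions(cond)
  pv <- water_vapor_pressure(cond$temperature)
  dry <- cond$barometric_pressure - pv
  if (dry <= 0)
    stop("barometric pressure (", format(cond$barometric_pressure),
         " mm Hg) does not exceed water vapor pressure (", format(pv),
         " mm Hg)")
  dry * cond$o2_mole_fraction
}

# Garcia & Gordon (1992) combined fit to the Benson & Krause oxygen
# solubility data, ml O2 per litre at 1 atm moist air. Scaled temperature
# polynomial plus salinity terms.
.gg_solubility_ml_l <- function(temperature, salinity) {
  ts <- log((298.15 - temperature) / (273.15 + temperature))
  a <- c(2.00907, 3.22014, 4.05010, 4.94457, -2.56847e-1, 3.88767)
  b <- c(-6.24523e-3, -7.37614e-3, -1.03410e-2, -8.17083e-3)
  c0 <- -4.88682e-7
  lnc <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 +
    a[6] * ts^5 +
    salinity * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) +
    c0 * salinity^2
  exp(lnc)
}

#' Dissolved oxygen concentration at 100% air saturation
#'
#' Oxygen solubility of seawater equilibrated with moist air, from the
#' Garcia--Gordon (1992) fit with Benson--Krause coefficients, converted from
#' ml L^-1 to mg L^-1 (1.42905 mg per ml O2 at STP) and corrected to the
#' actual barometric pressure by the dry-gas ratio
#' `(P - p_H2O) / (760 - p_H2O)`.
#'
#' @param cond A [gas_conditions()] object.
#' @return Dissolved O2 in mg L^-1 at 100% air saturation; strictly
#'   decreasing in both temperature and salinity.
#' @examples
#' o2_solubility(gas_conditions(28, 33, 1011, pressure_unit = "hPa"))
#' @export
o2_solubility <- function(cond) {
  cond <- as_gas_conditions(cond)
  pv <- water_vapor_pressure(cond$temperature)
  if (cond$barometric_pressure <= pv)
    stop("barometric pressure does not exceed water vapor pressure")
  c_std <- .gg_solubility_ml_l(cond$temperature, cond$salinity) * 1.42905
  # Garcia-Gordon assumes x_O2 = 0.20946 in standard air; rescale if the
  # caller overrides the mole fraction.
  c_std <- c_std * cond$o2_mole_fraction / 0.20946
  c_std * (cond$barometric_pressure - pv) / (760 - pv)
}

#' Convert percent air saturation to oxygen partial pressure
#'
#' @param percent Oxygen level as % of air saturation (non-negative).
#'   Vectorised.
#' @param cond A [gas_conditions()] object.
#' @return PO2 in mm Hg: `percent/100 * po2_at_full_air_saturation(cond)`.
#' @examples
#' percent_sat_to_po2(30.7, gas_conditions(28, 33, 758))
#' @export
percent_sat_to_po2 <- function(percent, cond) {
  if (any(percent < 0)) stop("percent air saturation must be non-negative")
  percent / 100 * po2_at_full_air_saturation(cond)
}

#' Convert percent air saturation to dissolved oxygen concentration
#'
#' @inheritParams percent_sat_to_po2
#' @return Dissolved O2 in mg L^-1: `percent/100 * o2_solubility(cond)`.
#' @examples
#' percent_sat_to_do(42, gas_conditions(28, 33, 758))
#' @export
percent_sat_to_do <- function(percent, cond) {
  if (any(percent < 0)) stop("percent air saturation must be non-negative")
  percent / 100 * o2_solubility(cond)
}

#' Convert oxygen partial pressure to percent air saturation
#'
#' @param po2 Oxygen partial pressure, mm Hg (non-negative). Vectorised.
#' @param cond A [gas_conditions()] object.
#' @return Percent air saturation.
#' @export
po2_to_percent_sat <- function(po2, cond) {
  if (any(po2 < 0)) stop("po2 must be non-negative")
  po2 / po2_at_full_air_saturation(cond) * 100
}

#' Convert dissolved oxygen concentration to percent air saturation
#'
#' @param do Dissolved O2, mg L^-1 (non-negative). Vectorised.
#' @param cond A [gas_conditions()] object.
#' @return Percent air saturation.
#' @export
do_to_percent_sat <- function(do, cond) {
  if (any(do < 0)) stop("dissolved O2 must be non-negative")
  do / o2_solubility(cond) * 100
}

#' Express an oxygen level in all three units
#'
#' @param percent Oxygen level as % of air saturation.
#' @param cond A [gas_conditions()] object.
#' @return An `oxygen_reading` data frame with columns
#'   `percent_air_saturation`, `po2` (mm Hg) and `dissolved_o2` (mg L^-1),
#'   mutually consistent under the package's conversions at `cond`.
#' @examples
#' oxygen_reading(c(42.0, 30.7, 23.8), gas_conditions(28, 33, 758))
#' @export
oxygen_reading <- function(percent, cond) {
  if (any(percent < 0)) stop("percent air saturation must be non-negative")
  out <- data.frame(
    percent_air_saturation = percent,
    po2 = percent_sat_to_po2(percent, cond),
    dissolved_o2 = percent_sat_to_do(percent, cond))
  class(out) <- c("oxygen_reading", "data.frame")
  out
}
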