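#' Convert a headspace N2O mixing ratio to mass of N2O-N
#'
#' Ideal-gas conversion: `conc * 1e-9` is the N2O mole fraction, the bottle
#' headspace holds `p * V / (R * T)` moles of gas, and each mole of N2O
#' carries two moles of N (28.013 g).
#'
#' @param conc_ppbv N2O mixing ratio (ppbv).
#' @param headspace_volume_L Headspace volume (L).
#' @param temperature_K Headspace temperature (K).
#' @param pressure_Pa Headspace pressure (Pa), default 1 atm.
#' @return Mass of N2O-N (ng); vectorised over all arguments.
#' @export
#' @examples
#' conc_to_mass(1000, 0.1229, 298.15) # ~140.7 ng N
conc_to_mass <- function(conc_ppbv, headspace_volume_L, temperature_K,
                         pressure_Pa = 101325) {
  .assert_number(conc_ppbv, "conc_ppbv", TRUE)
  .assert_number(headspace_volume_L, "headspace_volume_L", TRUE, allow_zero = FALSE)
  .assert_number(pressure_Pa, "pressure_Pa", TRUE, allow_zero = FALSE)
  if (!is.numeric(temperature_K) || anyNA(temperature_K) || any(temperature_K <= 0)) {
    stop("`temperature_K` must be positive", call. = FALSE)
  }
  if (any(temperature_K <= 270 | temperature_K >= 320)) {
    warning("temperature outside the plausible incubation range (270, 320) K",
            call. = FALSE)
  }
  moles_headspace <- pressure_Pa * headspace_volume_L * 1e-3 / (.R_GAS * temperature_K)
  # 1e-9 (ppbv) and 1e9 (g -> ng) cancel
  conc_ppbv * moles_headspace * .M_N2
}

#' Net N2O production rate from a paired enclosure measurement
#'
#' Assumes linear accumulation over the enclosure period (verified over 24 h
#' in the underlying incubation design) and expresses the rate per gram dry
#' soil and per day. Negative rates indicate net N2O uptake and are returned
#' unchanged.
#'
#' @param conc_t0_ppbv,conc_t24_ppbv Headspace mixing ratios at enclosure
#'   start and end (ppbv).
#' @param dry_mass_g Oven-dry soil mass (g).
#' @param enclosure_hours Enclosure duration (h).
#' @inheritParams conc_to_mass
#' @return Net rate (ng N2O-N g^-1 dry soil d^-1); vectorised.
#' @export
net_rate <- function(conc_t0_ppbv, conc_t24_ppbv, headspace_volume_L,
                     temperature_K, dry_mass_g, pressure_Pa = 101325,
                     enclosure_hours = 24) {
  if (any(dry_mass_g <= 0)) stop("`dry_mass_g` must be positive", call. = FALSE)
  if (any(enclosure_hours <= 0)) stop("`enclosure_hours` must be positive", call. = FALSE)
  delta <- conc_to_mass(conc_t24_ppbv, headspace_volume_L, temperature_K, pressure_Pa) -
    conc_to_mass(conc_t0_ppbv, headspace_volume_L, temperature_K, pressure_Pa)
  delta / dry_mass_g / (enclosure_hours / 24)
}

#' Net rates for a whole gas-measurement table
#'
#' Data-frame front end to [net_rate()]. Missing `headspace_volume_L` or
#' `pressure_Pa` columns fall back to the scenario geometry defaults; the
#' headspace temperature is taken as the incubation temperature.
#'
#' @param gas A tibble with the design key columns (`fertilization`,
#'   `temperature_C`, `replicate`, `c2h2_level`, `day`, `arm`) plus
#'   `conc_t0_ppbv` and `conc_t24_ppbv`, and optionally
#'   `headspace_volume_L` and `pressure_Pa`.
#' @param geometry A [bottle_geometry()] list.
#' @return The input tibble with a `rate_ngN_g_d` column appended.
#' @export
flux_rates <- function(gas, geometry = bottle_geometry()) {
  needed <- c("temperature_C", "conc_t0_ppbv", "conc_t24_ppbv")
  missing_cols <- setdiff(needed, names(gas))
  if (length(missing_cols)) {
    stop("gas table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  vol <- if ("headspace_volume_L" %in% names(gas)) {
    gas$headspace_volume_L
  } else {
    geometry$headspace_volume_L
  }
  prs <- if ("pressure_Pa" %in% names(gas)) gas$pressure_Pa else 101325
  gas$rate_ngN_g_d <- net_rate(
    gas$conc_t0_ppbv, gas$conc_t24_ppbv, vol,
    gas$temperature_C + 273.15, geometry$soil_dry_mass_g, prs,
    geometry$enclosure_hours
  )
  gas
}

#' Cumulative N2O emission by trapezoidal integration
#'
#' Integrates a net-rate time series from day 0 to its last measured day.
#' The rate between day 0 and the first measured day is extrapolated either
#' at the first day's rate (`day0 = "constant"`, default) or linearly from
#' zero (`day0 = "zero"`).
#'
#' @param day Strictly increasing measurement days.
#' @param rate Mean net rates (ng N g^-1 d^-1) at those days.
#' @param day0 Extrapolation rule for the unobserved day-0 rate.
#' @return Cumulative emission (ng N2O-N g^-1 dry soil).
#' @export
#' @examples
#' cumulative_emission(c(1, 3), c(0, 2)) # 0 over [0,1] + trapezoid 2 over [1,3]
cumulative_emission <- function(day, rate, day0 = c("constant", "zero")) {
  day0 <- match.arg(day0)
  if (length(day) == 0L) stop("empty rate series", call. = FALSE)
  if (length(day) != length(rate)) stop("`day` and `rate` lengths differ", call. = FALSE)
  if (anyDuplicated(day)) stop("duplicate days in rate series", call. = FALSE)
  ord <- order(day)
  day <- day[ord]; rate <- rate[ord]
  if (length(day) == 1L) {
    warning("single time point: cumulative emission is span * rate", call. = FALSE)
    return(day * rate)
  }
  if (day[1] > 0) {
    day <- c(0, day)
    rate <- c(if (day0 == "constant") rate[1] else 0, rate)
  }
  sum(diff(day) * (head(rate, -1) + tail(rate, -1)) / 2)
}
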