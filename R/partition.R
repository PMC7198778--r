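#' Gross N2O production and consumption from an acetylene triplet
#'
#' The three headspace treatments isolate the two gross processes:
#' 0 Pa C2H2 gives the undisturbed net rate, 10 Pa blocks autotrophic
#' nitrification, and 10 kPa additionally blocks N2O reduction. The gross
#' rates follow by arithmetic on the paired net rates:
#' consumption = r10k - r10, production = r10k - r10 + r0, so that
#' production - consumption = net holds exactly by construction.
#'
#' @param r0,r10,r10k Net rates (ng N g^-1 d^-1) under 0 Pa, 10 Pa and
#'   10 kPa C2H2 for the same replicate; vectorised.
#' @return A tibble with `production`, `consumption`, `net` and a logical
#'   `negative_flag` marking physically impossible (negative) gross
#'   estimates, which are retained untruncated.
#' @export
#' @examples
#' gross_rates(r0 = 2, r10 = 3, r10k = 5) # consumption 2, production 4
gross_rates <- function(r0, r10, r10k) {
  n <- length(r0)
  if (length(r10) != n || length(r10k) != n) {
    stop("r0, r10 and r10k must have equal length", call. = FALSE)
  }
  if (anyNA(r0) || anyNA(r10) || anyNA(r10k)) {
    stop("incomplete acetylene triplet: missing member rate", call. = FALSE)
  }
  consumption <- r10k - r10
  production <- consumption + r0
  tibble::tibble(
    production = production,
    consumption = consumption,
    net = r0,
    negative_flag = production < 0 | consumption < 0
  )
}

#' Cell-level gross process rates with uncertainty
#'
#' Aggregates replicate-level acetylene triplets into per-cell
#' (fertilization x temperature x day) estimates of gross production, gross
#' consumption and net rate. Two estimation modes are provided:
#'
#' * `"paired"` (default): gross rates are computed within each replicate
#'   (pairing the 0 Pa, 10 Pa and 10 kPa bottles of the same field-plot
#'   replicate) and the cell mean and standard error are taken over
#'   replicates. Pairing absorbs shared replicate-level variation.
#' * `"propagated"`: gross rates are computed from the treatment-level mean
#'   rates and their standard errors are propagated in quadrature from the
#'   contributing terms, `se_con = sqrt(se10k^2 + se10^2)` and
#'   `se_pro = sqrt(se10k^2 + se10^2 + se0^2)`.
#'
#' @param rates A long tibble with columns `fertilization`, `temperature_C`,
#'   `day`, `replicate`, `c2h2_level` (`"P0"`, `"P10"`, `"KP10"`) and
#'   `rate_ngN_g_d`. Extra columns are ignored.
#' @param mode Estimation mode, `"paired"` or `"propagated"`.
#' @return A tibble with one row per cell: means, standard errors, the
#'   consumption/production `ratio` (NA when production <= 0, flagged), `n`
#'   replicates, and flags for negative gross estimates.
#' @export
partition_rates <- function(rates, mode = c("paired", "propagated")) {
  mode <- match.arg(mode)
  trip <- triplet_table(rates)
  if (mode == "paired") {
    per_rep <- dplyr::bind_cols(
      trip[c("fertilization", "temperature_C", "day", "replicate")],
      gross_rates(trip$r0, trip$r10, trip$r10k)
    )
    out <- per_rep |>
      dplyr::group_by(.data$fertilization, .data$temperature_C, .data$day) |>
      dplyr::summarise(
        n = dplyr::n(),
        production_se = sd(.data$production) / sqrt(.data$n[1]),
        consumption_se = sd(.data$consumption) / sqrt(.data$n[1]),
        net_se = sd(.data$net) / sqrt(.data$n[1]),
        production = mean(.data$production),
        consumption = mean(.data$consumption),
        net = mean(.data$net),
        .groups = "drop"
      )
  } else {
    se <- function(x) sd(x) / sqrt(length(x))
    out <- trip |>
      dplyr::group_by(.data$fertilization, .data$temperature_C, .data$day) |>
      dplyr::summarise(
        n = dplyr::n(),
        production = mean(.data$r10k) - mean(.data$r10) + mean(.data$r0),
        consumption = mean(.data$r10k) - mean(.data$r10),
        net = mean(.data$r0),
        production_se = sqrt(se(.data$r10k)^2 + se(.data$r10)^2 + se(.data$r0)^2),
        consumption_se = sqrt(se(.data$r10k)^2 + se(.data$r10)^2),
        net_se = se(.data$r0),
        .groups = "drop"
      )
  }
  out$negative_flag <- out$production < 0 | out$consumption < 0
  out$ratio <- ifelse(out$production > 0, out$consumption / out$production, NA_real_)
  out$ratio_flag <- !is.na(out$ratio) & (out$ratio < 0 | out$ratio > 1)
  dplyr::relocate(
    out, "fertilization", "temperature_C", "day", "n",
    "production", "production_se", "consumption", "consumption_se",
    "net", "net_se", "ratio"
  )
}

# Reshape a long rates table into one row per replicate triplet (r0/r10/r10k),
# erroring on incomplete triplets.
triplet_table <- function(rates) {
  needed <- c("fertilization", "temperature_C", "day", "replicate",
              "c2h2_level", "rate_ngN_g_d")
  missing_cols <- setdiff(needed, names(rates))
  if (length(missing_cols)) {
    stop("rates table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rates <- rates[rates$c2h2_level %in% .C2H2_LEVELS, needed]
  if (nrow(rates) == 0L) stop("empty rates table", call. = FALSE)
  wide <- tidyr::pivot_wider(
    rates,
    names_from = "c2h2_level", values_from = "rate_ngN_g_d"
  )
  for (lev in .C2H2_LEVELS) if (!lev %in% names(wide)) wide[[lev]] <- NA_real_
  if (anyNA(wide[.C2H2_LEVELS])) {
    stop("incomplete acetylene triplet(s): every cell replicate needs P0, ",
         "P10 and KP10 rates", call. = FALSE)
  }
  dplyr::rename(wide, r0 = "P0", r10 = "P10", r10k = "KP10")
}

#' Consumption/production ratio, the N2/(N2O + N2) product ratio
#'
#' The fraction of gross N2O production that is further reduced to N2 before
#' escaping the soil. Physically meaningful values lie in `[0, 1]`; values
#' outside are returned with a warning.
#'
#' @param production,consumption Gross rates (same units); vectorised.
#' @return Dimensionless ratio(s).
#' @export
consumption_fraction <- function(production, consumption) {
  if (any(production <= 0)) {
    stop("ratio undefined: gross production must be > 0", call. = FALSE)
  }
  ratio <- consumption / production
  if (any(ratio < 0 | ratio > 1)) {
    warning("consumption/production ratio outside [0, 1]", call. = FALSE)
  }
  ratio
}

#' Contribution of autotrophic nitrification to net N2O production
#'
#' The difference between the 0 Pa and 10 Pa treatment means estimates the
#' N2O produced by autotrophic nitrification (the pathway blocked by 10 Pa
#' C2H2). Negative estimates (sampling noise) are censored to zero in the
#' reported share while the raw value is retained.
#'
#' @param r0_mean,r10_mean Treatment-mean net rates under 0 Pa and 10 Pa.
#' @return A tibble with `rate_raw`, `rate` (censored), `share` (of the net
#'   rate, when `r0_mean > 0`) and `censored_flag`.
#' @export
nitrification_share <- function(r0_mean, r10_mean) {
  raw <- r0_mean - r10_mean
  censored <- pmax(raw, 0)
  tibble::tibble(
    rate_raw = raw,
    rate = censored,
    share = ifelse(r0_mean > 0, censored / r0_mean, NA_real_),
    censored_flag = raw < 0
  )
}

#' Fraction of nitrate buildup not explained by initial ammonium
#'
#' If all initial ammonium were nitrified, it could account for at most
#' `initial_nh4` of the observed nitrate increase; the remainder must stem
#' from heterotrophic nitrification or mineralisation-coupled nitrification.
#' Computed as `100 * (1 - initial_nh4 / delta_no3)`, floored at 0.
#'
#' @param initial_nh4 Initial NH4+-N concentration (ug g^-1).
#' @param delta_no3 Net NO3--N concentration increase (ug g^-1), > 0.
#' @return Percentage in `[0, 100]`; vectorised.
#' @export
nitrate_buildup_fraction <- function(initial_nh4, delta_no3) {
  .assert_number(initial_nh4, "initial_nh4", TRUE)
  if (any(delta_no3 <= 0)) {
    stop("`delta_no3` must be > 0", call. = FALSE)
  }
  pmax(0, 100 * (1 - initial_nh4 / delta_no3))
}
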