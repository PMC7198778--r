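#' Enumerate the factorial microcosm design
#'
#' Builds the full Cartesian product of fertilization regimes, incubation
#' temperatures, replicates, headspace acetylene levels and sampling days for
#' one experimental arm, one row per serum bottle. The canonical study layout
#' is 3 fertilization regimes (CT, NPK, MNPK) x 3 temperatures (15/25/35
#' degC) x 4 replicates, with 0 Pa bottles monitored through the incubation
#' and fresh 10 Pa / 10 kPa bottles enclosed on each campaign day.
#'
#' @param fertilizations Character vector of fertilization labels.
#' @param temperatures Integer vector of incubation temperatures (degC). May
#'   be `NA` for the day-0 baseline arm, which is sampled before bottles are
#'   assigned to incubators.
#' @param replicates Number of replicates per cell.
#' @param c2h2_levels Acetylene partial-pressure levels, subset of
#'   `c("P0", "P10", "KP10")` (0 Pa, 10 Pa, 10 kPa).
#' @param days Integer vector of sampling days.
#' @param arm Experimental arm, one of `"net_monitoring"`, `"c2h2_campaign"`,
#'   `"destructive"`.
#' @param fresh_per_campaign Logical; when `TRUE` (default) the C2H2 campaign
#'   bottles are fresh microcosms on every campaign day (each day x level x
#'   cell is a distinct bottle). When `FALSE` the same bottles are re-enclosed
#'   on every campaign day and `bottle_id` is shared across days.
#'
#' @return A tibble with columns `fertilization`, `temperature_C`,
#'   `replicate`, `c2h2_level`, `day`, `arm`, `bottle_id`, sorted by
#'   fertilization, temperature, replicate, acetylene level and day.
#' @export
#' @examples
#' nrow(enumerate_design(days = 3))                                    # 36
#' nrow(enumerate_design(c2h2_levels = c("P10", "KP10"), days = 3))    # 72
enumerate_design <- function(fertilizations = c("CT", "NPK", "MNPK"),
                             temperatures = c(15L, 25L, 35L),
                             replicates = 4L,
                             c2h2_levels = "P0",
                             days = c(3L, 15L, 30L),
                             arm = "net_monitoring",
                             fresh_per_campaign = TRUE) {
  if (length(fertilizations) < 1L || length(temperatures) < 1L ||
      length(c2h2_levels) < 1L || length(days) < 1L) {
    stop("all design factors need at least one level", call. = FALSE)
  }
  if (!is.numeric(replicates) || replicates < 1L) {
    stop("`replicates` must be >= 1", call. = FALSE)
  }
  arm <- match.arg(arm, .ARM_LEVELS)
  bad <- setdiff(c2h2_levels, .C2H2_LEVELS)
  if (length(bad)) {
    stop("unknown c2h2 level(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }

  units <- tidyr::expand_grid(
    fertilization = as.character(fertilizations),
    temperature_C = as.integer(temperatures),
    replicate = seq_len(replicates),
    c2h2_level = as.character(c2h2_levels),
    day = as.integer(days)
  )
  units <- dplyr::arrange(
    units,
    factor(.data$fertilization, levels = unique(fertilizations)),
    .data$temperature_C, .data$replicate,
    factor(.data$c2h2_level, levels = .C2H2_LEVELS), .data$day
  )
  units$arm <- arm

  key_cols <- c("fertilization", "temperature_C", "replicate", "c2h2_level")
  bottle_key <- if (fresh_per_campaign && arm == "c2h2_campaign") {
    c(key_cols, "day")
  } else {
    key_cols
  }
  units$bottle_id <- do.call(paste, c(units[bottle_key], sep = "/"))
  units$bottle_id <- paste(substr(arm, 1, 3), units$bottle_id, sep = "/")
  units
}

#' Check a design for balanced replication
#'
#' Counts replicates per design cell (fertilization x temperature x acetylene
#' level x day x arm) and flags cells that depart from the modal count.
#'
#' @param units A design tibble as produced by [enumerate_design()].
#' @return A tibble of per-cell counts with a logical `deficient` column;
#'   attribute `balanced` is `TRUE` when all counts are equal.
#' @export
validate_balance <- function(units) {
  if (!is.data.frame(units) || nrow(units) == 0L) {
    stop("`units` must be a non-empty design table", call. = FALSE)
  }
  counts <- dplyr::count(
    units, .data$fertilization, .data$temperature_C, .data$c2h2_level,
    .data$day, .data$arm,
    name = "n_replicates"
  )
  modal <- as.integer(names(which.max(table(counts$n_replicates))))
  counts$deficient <- counts$n_replicates != modal
  attr(counts, "balanced") <- !any(counts$deficient)
  attr(counts, "modal_n") <- modal
  if (any(counts$deficient)) {
    warning(sum(counts$deficient), " design cell(s) depart from n = ", modal,
            call. = FALSE)
  }
  counts
}

#' Microcosm bottle geometry and enclosure settings
#'
#' @param soil_dry_mass_g Oven-dry soil mass per bottle (g).
#' @param bottle_volume_ml Serum-bottle volume (mL).
#' @param bulk_density_g_cm3 Assumed soil bulk density used to derive the
#'   headspace volume from the bottle volume (g cm^-3).
#' @param moisture_whc Soil moisture as a fraction of water-holding capacity
#'   (recorded only; it does not enter the flux arithmetic).
#' @param enclosure_hours Duration of the sealed enclosure (h).
#' @return A list of class `n2o_scenario_geometry`, including the derived
#'   `headspace_volume_L`.
#' @export
bottle_geometry <- function(soil_dry_mass_g = 18,
                            bottle_volume_ml = 125,
                            bulk_density_g_cm3 = 1.3,
                            moisture_whc = 0.5,
                            enclosure_hours = 24) {
  .assert_number(soil_dry_mass_g, "soil_dry_mass_g", TRUE, allow_zero = FALSE)
  .assert_number(bottle_volume_ml, "bottle_volume_ml", TRUE, allow_zero = FALSE)
  .assert_number(enclosure_hours, "enclosure_hours", TRUE, allow_zero = FALSE)
  soil_volume_ml <- soil_dry_mass_g / bulk_density_g_cm3
  if (bottle_volume_ml <= soil_volume_ml) {
    stop("bottle volume must exceed the soil displacement volume", call. = FALSE)
  }
  structure(
    list(
      soil_dry_mass_g = soil_dry_mass_g,
      bottle_volume_ml = bottle_volume_ml,
      bulk_density_g_cm3 = bulk_density_g_cm3,
      moisture_whc = moisture_whc,
      enclosure_hours = enclosure_hours,
      headspace_volume_L = (bottle_volume_ml - soil_volume_ml) / 1000
    ),
    class = "n2o_scenario_geometry"
  )
}
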