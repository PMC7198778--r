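#' Fit a qPCR standard curve and compute amplification efficiency
#'
#' Ordinary least squares of Cq on log10 template copies over a serial
#' dilution. The amplification efficiency is `10^(-1/slope) - 1`; a perfect
#' doubling per cycle corresponds to a slope of -3.3219 (efficiency 1).
#' A warning is raised when R^2 does not exceed 0.99, the usual quality bar
#' for quantitative work.
#'
#' @param log10_copies log10 template copies of the dilution points.
#' @param cq Measured quantification cycles.
#' @return An object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `cq_range`, `n`.
#' @export
#' @examples
#' # the efficiency reported for a slope of -3.679 is 87%
#' fit_standard_curve(5:1, -3.679 * (5:1) + 38)$efficiency
fit_standard_curve <- function(log10_copies, cq) {
  if (length(log10_copies) != length(cq)) {
    stop("`log10_copies` and `cq` lengths differ", call. = FALSE)
  }
  if (length(cq) < 3L) stop("need >= 3 dilution points", call. = FALSE)
  if (diff(range(log10_copies)) < 2) {
    stop("dilution series must span >= 2 orders of magnitude", call. = FALSE)
  }
  fit <- lm(cq ~ log10_copies)
  slope <- unname(coef(fit)[2L])
  if (slope >= 0) {
    stop("invalid standard curve: slope must be negative (Cq decreases ",
         "with template)", call. = FALSE)
  }
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  if (r2 <= 0.99) {
    warning(sprintf("standard-curve R^2 = %.4f does not exceed 0.99", r2),
            call. = FALSE)
  }
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1L]),
         r_squared = r2, efficiency = 10^(-1 / slope) - 1,
         cq_range = range(cq), n = length(cq)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: Cq = %.3f %+.4f * log10(copies), R2 = %.4f, efficiency = %.1f%%\n",
    x$intercept, x$slope, x$r_squared, 100 * x$efficiency
  ))
  invisible(x)
}

#' Gene copy number per gram dry soil from a Cq value
#'
#' Inverts the standard curve (`copies = 10^((cq - intercept) / slope)`)
#' and scales from the reaction to the soil: template volume up to the
#' eluate, times the pre-PCR dilution, divided by the dry mass extracted.
#' The DNA extraction input is fresh soil; `moisture` converts it to a
#' dry-mass basis so abundances share units with the process rates.
#'
#' @param cq Quantification cycle(s); vectorised.
#' @param curve A [fit_standard_curve()] object.
#' @param elution_volume_uL DNA elution volume of the extraction (uL);
#'   kit-specific, no default.
#' @param dilution Fold dilution of the eluate before PCR.
#' @param template_volume_uL Template volume per reaction (uL).
#' @param extraction_mass_g Fresh soil mass extracted (g).
#' @param moisture Gravimetric water fraction of the extracted soil
#'   (fresh-mass basis), used to express copies per g dry soil.
#' @param warn_extrapolation Warn when `cq` falls outside the calibrated
#'   range of the standards.
#' @return Copies per gram dry soil; vectorised over `cq`.
#' @export
quantify <- function(cq, curve, elution_volume_uL, dilution = 20,
                     template_volume_uL = 2, extraction_mass_g = 0.5,
                     moisture = 0, warn_extrapolation = TRUE) {
  stopifnot(inherits(curve, "standard_curve"))
  if (missing(elution_volume_uL) || elution_volume_uL <= 0) {
    stop("`elution_volume_uL` is required and must be positive", call. = FALSE)
  }
  if (template_volume_uL <= 0 || extraction_mass_g <= 0 || dilution <= 0) {
    stop("volumes, dilution and extraction mass must be positive", call. = FALSE)
  }
  if (moisture < 0 || moisture >= 1) stop("`moisture` must be in [0, 1)", call. = FALSE)
  if (warn_extrapolation &&
      any(cq < curve$cq_range[1L] | cq > curve$cq_range[2L], na.rm = TRUE)) {
    warning("Cq value(s) outside the calibrated standard-curve range; ",
            "quantification is an extrapolation", call. = FALSE)
  }
  copies_rxn <- 10^((cq - curve$intercept) / curve$slope)
  dry_mass <- extraction_mass_g * (1 - moisture)
  copies_rxn * dilution * (elution_volume_uL / template_volume_uL) / dry_mass
}

#' Summarise technical qPCR replicates per sample
#'
#' Back-transforms each technical replicate's Cq to copies per g dry soil,
#' then reports the mean and the coefficient of variation on the copy scale.
#'
#' @param qpcr A tibble with columns `sample_id`, `gene`, `cq` (one row per
#'   technical replicate).
#' @param curves A named list of [fit_standard_curve()] objects, one per
#'   gene.
#' @param ntc_cutoff Cq above which a reaction is treated as a non-detect
#'   (flagged, excluded from the mean); `NA` Cqs are non-detects too.
#' @inheritParams quantify
#' @return A tibble with `sample_id`, `gene`, `copies_per_g`, `cv`,
#'   `n_detect`, `ntc_flag`.
#' @export
summarise_abundance <- function(qpcr, curves, elution_volume_uL,
                                dilution = 20, template_volume_uL = 2,
                                extraction_mass_g = 0.5, moisture = 0,
                                ntc_cutoff = 35) {
  stopifnot(all(c("sample_id", "gene", "cq") %in% names(qpcr)))
  qpcr |>
    dplyr::group_by(.data$sample_id, .data$gene) |>
    dplyr::group_modify(function(d, key) {
      detect <- !is.na(d$cq) & d$cq <= ntc_cutoff
      copies <- if (any(detect)) {
        quantify(d$cq[detect], curves[[key$gene]], elution_volume_uL,
                 dilution, template_volume_uL, extraction_mass_g, moisture,
                 warn_extrapolation = FALSE)
      } else {
        numeric(0)
      }
      tibble::tibble(
        copies_per_g = if (length(copies)) mean(copies) else 0,
        cv = if (length(copies) > 1L) sd(copies) / mean(copies) else NA_real_,
        n_detect = sum(detect),
        ntc_flag = any(!detect)
      )
    }) |>
    dplyr::ungroup()
}
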