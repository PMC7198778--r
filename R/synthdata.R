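#' Default calibrated microcosm scenario
#'
#' The packaged study configuration: 3 fertilization regimes (CT, NPK,
#' MNPK) x 3 temperatures (15/25/35 degC) x 4 replicates, net-rate
#' monitoring on days 1-30 and acetylene campaigns on days 3, 15 and 30.
#' The per-cell truth table encodes the qualitative temperature-response
#' contrasts of the three regimes -- CT gross consumption rises with
#' temperature early in the incubation and falls late; NPK gross production
#' responds strongly to temperature at days 15/30 while its consumption is
#' nearly temperature-flat; MNPK peaks at 25 degC -- and is calibrated so
#' the true consumption/production ratios span 0.48-0.75 with mean exactly
#' 0.62 and the CT truth correlates production with consumption at ~0.98.
#'
#' @return A list of class `n2o_scenario` (truth table, variance model,
#'   inhibition efficiencies, geometry, nutrient / community / qPCR
#'   settings).
#' @export
scenario_default <- function() {
  truth <- tibble::tibble(
    fertilization = rep(.FERT_LEVELS, each = 9L),
    day = rep(rep(c(3L, 15L, 30L), each = 3L), times = 3L),
    temperature_C = rep(c(15L, 25L, 35L), times = 9L),
    production = c(
      8.5, 12, 18,   5, 6, 5.5,      3.4, 3.5, 4,    # CT
      10, 16, 24,    6, 9, 13,       3.5, 5.5, 8,    # NPK
      10, 15, 13.5,  5.5, 7.5, 7,    3, 4.5, 4.2     # MNPK
    ),
    ratio = c(
      .52, .64, .75,   .70, .60, .53,   .75, .61, .53,   # CT
      .62, .60, .58,   .655, .545, .48, .70, .53, .49,   # NPK
      .68, .72, .70,   .645, .685, .62, .615, .655, .59  # MNPK
    )
  )
  truth$f_nit <- ifelse(
    truth$fertilization == "NPK" & truth$temperature_C == 35 & truth$day == 15,
    0.30, 0.05
  )
  scenario_build(truth)
}

#' Null scenario with all treatment effects removed
#'
#' Every cell shares the same gross production, consumption ratio,
#' community composition and gene abundance; the true Q10 of every process
#' is exactly 1. Used to calibrate the type-I error of the bootstrap,
#' Mantel and PERMANOVA procedures.
#'
#' @param production Common gross production rate (ng N g^-1 d^-1).
#' @param ratio Common consumption/production ratio.
#' @param replicates Replicates per cell.
#' @param fertilizations,temperatures,campaign_days Factor levels (kept
#'   small in calibration loops for speed).
#' @param replicate_cv Lognormal replicate coefficient of variation.
#' @param noise_sd Gaussian measurement noise on rates (rate units).
#' @return An `n2o_scenario` list.
#' @export
scenario_null <- function(production = 6, ratio = 0.5, replicates = 4L,
                          fertilizations = c("CT", "NPK", "MNPK"),
                          temperatures = c(15L, 25L, 35L),
                          campaign_days = c(3L, 15L, 30L),
                          replicate_cv = 0.15, noise_sd = 0.25) {
  truth <- tidyr::expand_grid(
    fertilization = fertilizations,
    day = as.integer(campaign_days),
    temperature_C = as.integer(temperatures)
  )
  truth$production <- production
  truth$ratio <- ratio
  truth$f_nit <- 0
  sc <- scenario_build(truth,
                       replicates = replicates,
                       temperatures = as.integer(temperatures),
                       campaign_days = as.integer(campaign_days),
                       net_days = sort(unique(c(1L, as.integer(campaign_days)))),
                       replicate_cv = replicate_cv, noise_sd = noise_sd)
  sc$community$sd_fert <- 0
  sc$community$sd_time <- 0
  sc$community$sd_temp <- 0
  for (g in names(sc$qpcr$genes)) {
    sc$qpcr$genes[[g]]$fert_mult[] <- 1
    sc$qpcr$genes[[g]]$time_mult[] <- 1
    sc$qpcr$genes[[g]]$temp_trend[] <- 0
  }
  sc$null <- TRUE
  sc
}

# Assemble a scenario list around a truth table.
scenario_build <- function(truth,
                           replicates = 4L,
                           temperatures = c(15L, 25L, 35L),
                           campaign_days = c(3L, 15L, 30L),
                           net_days = c(1L, 3L, 5L, 7L, 10L, 15L, 20L, 25L, 30L),
                           replicate_cv = 0.15, noise_sd = 0.25) {
  structure(
    list(
      truth = truth,
      fertilizations = unique(truth$fertilization),
      temperatures = temperatures,
      replicates = replicates,
      campaign_days = campaign_days,
      net_days = net_days,
      replicate_cv = replicate_cv,
      noise_sd = noise_sd,
      eta_nit = 1, eta_cons = 1,
      geometry = bottle_geometry(),
      ambient_ppbv = 330,
      nutrients = list(
        initial_nh4 = c(CT = 1.19, NPK = 13.05, MNPK = 3.26),
        initial_no3 = c(CT = 10, NPK = 25, MNPK = 25),
        delta_no3 = c(CT = 68, NPK = 101, MNPK = 90),
        nh4_remaining_d30 = c(CT = 0.20, NPK = 0.76, MNPK = 0.64),
        cv = 0.05
      ),
      community = list(
        n_bins = 40L, concentration = 50,
        # per-gene effect scales on log bin weights; nosZI shifts strongly
        # with fertilization, nosZII with sampling time
        genes = list(
          nosZI = list(sd_fert = 1.2, sd_time = 0.30, sd_temp = 0.30),
          nosZII = list(sd_fert = 0.08, sd_time = 1.2, sd_temp = 0.45)
        ),
        sd_fert = NA, sd_time = NA, sd_temp = NA,  # overrides (null scenario)
        total_height = 30000, height_sdlog = 0.2, jitter_bp = 0.4
      ),
      qpcr = list(
        elution_volume_uL = 100, dilution = 20, template_volume_uL = 2,
        extraction_mass_g = 0.5, moisture = 0,
        standards_log10 = 3:8, standards_cq_sd = 0.05, cq_sd = 0.08,
        sdlog_abundance = 0.15,
        genes = list(
          nosZI = list(
            slope = -3.679, intercept = 38.5, base_copies = 1e8,
            fert_mult = c(CT = 1, NPK = 0.45, MNPK = 1.1),
            time_mult = c(`0` = 1, `3` = 1.1, `15` = 0.5, `30` = 0.9),
            temp_trend = c(`0` = 0, `3` = 0.012, `15` = 0.012, `30` = -0.01)
          ),
          nosZII = list(
            slope = -1 / log10(1.902), intercept = 39.0, base_copies = 1.5e7,
            fert_mult = c(CT = 1, NPK = 0.12, MNPK = 0.9),
            time_mult = c(`0` = 1, `3` = 1.1, `15` = 0.45, `30` = 0.25),
            temp_trend = c(`0` = 0, `3` = 0, `15` = 0, `30` = 0)
          )
        )
      ),
      null = FALSE
    ),
    class = "n2o_scenario"
  )
}

#' Generate a complete synthetic microcosm study
#'
#' Draws a full study from a scenario: replicate-level true gross rates
#' (lognormal replicate effect shared across the acetylene triplet of a
#' field-plot replicate), expected net rates per headspace treatment
#' following the inhibition semantics (`E[r0] = P - C`,
#' `E[r10] = P(1 - eta_nit f_nit) - C`,
#' `E[r10k] = P(1 - eta_nit f_nit) - (1 - eta_cons) C`), additive Gaussian
#' measurement noise, and an inversion of the flux arithmetic to emit
#' headspace concentration pairs. Optionally adds nutrient trajectories,
#' Dirichlet T-RFLP peak tables for both nosZ clades, and qPCR standard /
#' sample Cq tables. Fully reproducible: the same seed yields an identical
#' study.
#'
#' @param scenario An `n2o_scenario` from [scenario_default()] or
#'   [scenario_null()].
#' @param seed Integer seed (required).
#' @param components Which data blocks to generate, subset of
#'   `c("gas", "nutrients", "community", "qpcr")`.
#' @return A list of class `n2o_study` with tibbles `gas`, `truth_cells`,
#'   `truth_replicates`, and (as requested) `nutrients`, `peaks_nosZI`,
#'   `peaks_nosZII`, `standards`, `qpcr`, plus the scenario echo and seed.
#' @export
generate_study <- function(scenario, seed,
                           components = c("gas", "nutrients", "community", "qpcr")) {
  stopifnot(inherits(scenario, "n2o_scenario"))
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  components <- match.arg(components, several.ok = TRUE)
  set.seed(seed)
  sc <- scenario

  miss <- setdiff(
    paste(rep(sc$fertilizations, each = length(sc$temperatures) * length(sc$campaign_days)),
          rep(rep(sc$temperatures, each = length(sc$campaign_days)),
              times = length(sc$fertilizations)),
          rep(sc$campaign_days, times = length(sc$fertilizations) * length(sc$temperatures))),
    paste(sc$truth$fertilization, sc$truth$temperature_C, sc$truth$day)
  )
  if (length(miss)) {
    stop("scenario truth table lacks cell(s): ", paste(miss, collapse = "; "),
         call. = FALSE)
  }

  # replicate effects: one multiplier per field-plot replicate within each
  # fertilization x temperature cell, shared across arms and days
  sdl <- sqrt(log(1 + sc$replicate_cv^2))
  reps <- tidyr::expand_grid(
    fertilization = sc$fertilizations,
    temperature_C = sc$temperatures,
    replicate = seq_len(sc$replicates)
  )
  reps$L <- exp(rnorm(nrow(reps), -sdl^2 / 2, sdl))

  interp <- function(day, x, y, log_scale = TRUE) {
    if (length(x) == 1L) return(rep(y, length(day)))
    if (log_scale) {
      exp(approx(x, log(y), xout = pmax(day, min(x)), rule = 2)$y)
    } else {
      approx(x, y, xout = pmax(day, min(x)), rule = 2)$y
    }
  }
  truth_at <- function(f, temp, day) {
    tt <- sc$truth[sc$truth$fertilization == f & sc$truth$temperature_C == temp, ]
    tt <- tt[order(tt$day), ]
    P <- interp(day, tt$day, tt$production)
    rho <- interp(day, tt$day, tt$ratio, log_scale = FALSE)
    fn <- interp(day, tt$day, tt$f_nit, log_scale = FALSE)
    tibble::tibble(production = P, consumption = rho * P, ratio = rho, f_nit = fn)
  }

  out <- list(scenario = sc, seed = seed)

  ## --- gas / rates -------------------------------------------------------
  cellrep <- dplyr::cross_join(
    reps,
    tibble::tibble(day = sort(unique(c(sc$net_days, sc$campaign_days))))
  )
  tr <- dplyr::bind_rows(lapply(seq_len(nrow(cellrep)), function(i) {
    truth_at(cellrep$fertilization[i], cellrep$temperature_C[i], cellrep$day[i])
  }))
  cellrep <- dplyr::bind_cols(cellrep, tr)
  cellrep$P_rep <- cellrep$production * cellrep$L
  cellrep$C_rep <- cellrep$consumption * cellrep$L

  rows <- list()
  net <- cellrep[cellrep$day %in% sc$net_days, ]
  net$c2h2_level <- "P0"
  net$arm <- "net_monitoring"
  net$rate_true <- net$P_rep - net$C_rep
  rows[[1L]] <- net
  camp <- cellrep[cellrep$day %in% sc$campaign_days, ]
  inhib <- 1 - sc$eta_nit * camp$f_nit
  p10 <- camp
  p10$c2h2_level <- "P10"
  p10$arm <- "c2h2_campaign"
  p10$rate_true <- camp$P_rep * inhib - camp$C_rep
  rows[[2L]] <- p10
  p10k <- camp
  p10k$c2h2_level <- "KP10"
  p10k$arm <- "c2h2_campaign"
  p10k$rate_true <- camp$P_rep * inhib - (1 - sc$eta_cons) * camp$C_rep
  rows[[3L]] <- p10k
  gas <- dplyr::bind_rows(rows)
  gas$rate_ngN_g_d <- gas$rate_true + rnorm(nrow(gas), 0, sc$noise_sd)

  # invert the flux arithmetic into headspace concentration pairs
  geom <- sc$geometry
  t_k <- gas$temperature_C + 273.15
  ng_per_ppbv <- conc_to_mass(1, geom$headspace_volume_L, t_k)
  delta_ng <- gas$rate_ngN_g_d * geom$soil_dry_mass_g * (geom$enclosure_hours / 24)
  gas$conc_t0_ppbv <- pmax(0, sc$ambient_ppbv + runif(nrow(gas), -5, 5))
  gas$conc_t24_ppbv <- gas$conc_t0_ppbv + delta_ng / ng_per_ppbv
  if (any(gas$conc_t24_ppbv < 0)) {
    warning("net uptake exceeded the ambient headspace pool in ",
            sum(gas$conc_t24_ppbv < 0), " bottle(s)", call. = FALSE)
  }
  gas$headspace_volume_L <- geom$headspace_volume_L
  gas$pressure_Pa <- 101325

  out$gas <- dplyr::select(
    gas, "fertilization", "temperature_C", "replicate", "c2h2_level",
    "day", "arm", "conc_t0_ppbv", "conc_t24_ppbv", "headspace_volume_L",
    "pressure_Pa"
  )
  out$truth_replicates <- dplyr::select(
    cellrep[cellrep$day %in% sc$campaign_days, ],
    "fertilization", "temperature_C", "replicate", "day",
    "P_rep", "C_rep", "f_nit"
  )
  out$truth_cells <- dplyr::distinct(
    sc$truth, .data$fertilization, .data$temperature_C, .data$day,
    .data$production, .data$ratio, .data$f_nit
  )

  ## --- nutrients ---------------------------------------------------------
  if ("nutrients" %in% components) out$nutrients <- gen_nutrients(sc)

  ## --- community / qPCR sample set --------------------------------------
  if (any(c("community", "qpcr") %in% components)) {
    samp <- dplyr::bind_rows(
      tidyr::expand_grid(fertilization = sc$fertilizations,
                         temperature_C = NA_integer_, replicate = seq_len(sc$replicates),
                         day = 0L),
      tidyr::expand_grid(fertilization = sc$fertilizations,
                         temperature_C = sc$temperatures, replicate = seq_len(sc$replicates),
                         day = sc$campaign_days)
    )
    samp$sample_id <- paste0(
      samp$fertilization, "_",
      ifelse(is.na(samp$temperature_C), "pre", paste0("T", samp$temperature_C)),
      "_d", samp$day, "_r", samp$replicate
    )
    out$samples <- samp
    if ("community" %in% components) {
      out$peaks_nosZI <- gen_peaks(sc, samp, "nosZI")
      out$peaks_nosZII <- gen_peaks(sc, samp, "nosZII")
    }
    if ("qpcr" %in% components) {
      std <- gen_standards(sc)
      out$standards <- std
      out$qpcr <- gen_qpcr(sc, samp)
    }
  }

  structure(out, class = "n2o_study")
}

#' Generate a null study for calibration
#'
#' @param seed Integer seed.
#' @param ... Passed to [scenario_null()].
#' @inheritParams generate_study
#' @return An `n2o_study` with no treatment effects.
#' @export
generate_null_study <- function(seed, components = "gas", ...) {
  generate_study(scenario_null(...), seed = seed, components = components)
}

gen_nutrients <- function(sc) {
  nut <- sc$nutrients
  grid <- dplyr::bind_rows(
    tidyr::expand_grid(fertilization = sc$fertilizations,
                       temperature_C = NA_integer_,
                       replicate = seq_len(sc$replicates), day = 0L),
    tidyr::expand_grid(fertilization = sc$fertilizations,
                       temperature_C = sc$temperatures,
                       replicate = seq_len(sc$replicates),
                       day = setdiff(sort(unique(c(0L, sc$campaign_days))), 0L))
  )
  tshape <- function(day, k = 0.1) (1 - exp(-k * day)) / (1 - exp(-k * 30))
  tempfac <- ifelse(is.na(grid$temperature_C), 1,
                    0.85 + 0.015 * (grid$temperature_C - 15))
  rem30 <- nut$nh4_remaining_d30[grid$fertilization]
  nh4 <- nut$initial_nh4[grid$fertilization] *
    (1 - (1 - rem30) * tshape(grid$day, 0.15) * tempfac)
  no3 <- nut$initial_no3[grid$fertilization] +
    nut$delta_no3[grid$fertilization] * tshape(grid$day) * tempfac
  grid$nh4_ug_g <- pmax(0, nh4 * exp(rnorm(nrow(grid), 0, nut$cv)))
  grid$no3_ug_g <- pmax(0, no3 * exp(rnorm(nrow(grid), 0, nut$cv)))
  grid
}

gen_peaks <- function(sc, samp, gene) {
  cm <- sc$community
  g <- cm$genes[[gene]]
  sd_fert <- if (is.na(cm$sd_fert)) g$sd_fert else cm$sd_fert
  sd_time <- if (is.na(cm$sd_time)) g$sd_time else cm$sd_time
  sd_temp <- if (is.na(cm$sd_temp)) g$sd_temp else cm$sd_temp

  centers <- 60 + cumsum(runif(cm$n_bins, 4, 12))
  w0 <- rnorm(cm$n_bins, 0, 1)
  ferts <- unique(samp$fertilization)
  days <- sort(unique(samp$day))
  temps <- sort(unique(na.omit(samp$temperature_C)))
  eff_f <- matrix(rnorm(length(ferts) * cm$n_bins, 0, sd_fert),
                  length(ferts), dimnames = list(ferts))
  eff_d <- matrix(rnorm(length(days) * cm$n_bins, 0, sd_time),
                  length(days), dimnames = list(days))
  eff_t <- matrix(rnorm(length(temps) * cm$n_bins, 0, sd_temp),
                  length(temps), dimnames = list(temps))

  peaks <- vector("list", nrow(samp))
  for (i in seq_len(nrow(samp))) {
    lw <- w0 + eff_f[samp$fertilization[i], ] + eff_d[as.character(samp$day[i]), ]
    if (!is.na(samp$temperature_C[i])) {
      lw <- lw + eff_t[as.character(samp$temperature_C[i]), ]
    }
    alpha <- cm$concentration * exp(lw) / sum(exp(lw))
    y <- rgamma(cm$n_bins, shape = alpha, rate = 1)
    y <- y / sum(y)
    total <- exp(rnorm(1, log(cm$total_height), cm$height_sdlog))
    height <- round(y * total)
    keep <- height > 0
    peaks[[i]] <- tibble::tibble(
      sample_id = samp$sample_id[i],
      fragment_bp = round(centers[keep] + runif(sum(keep), -cm$jitter_bp, cm$jitter_bp), 1),
      height = height[keep]
    )
  }
  dplyr::bind_rows(peaks)
}

gen_standards <- function(sc) {
  qp <- sc$qpcr
  dplyr::bind_rows(lapply(names(qp$genes), function(gene) {
    g <- qp$genes[[gene]]
    tibble::tibble(
      gene = gene,
      log10_copies = as.numeric(qp$standards_log10),
      cq = g$intercept + g$slope * log10_copies +
        rnorm(length(qp$standards_log10), 0, qp$standards_cq_sd)
    )
  }))
}

gen_qpcr <- function(sc, samp) {
  qp <- sc$qpcr
  dry_mass <- qp$extraction_mass_g * (1 - qp$moisture)
  dplyr::bind_rows(lapply(names(qp$genes), function(gene) {
    g <- qp$genes[[gene]]
    tmul <- g$time_mult[as.character(samp$day)]
    fmul <- g$fert_mult[samp$fertilization]
    trend <- g$temp_trend[as.character(samp$day)]
    tempmul <- ifelse(is.na(samp$temperature_C), 1,
                      exp(trend * (samp$temperature_C - 25)))
    copies_g <- unname(g$base_copies * fmul * tmul * tempmul *
                         exp(rnorm(nrow(samp), 0, qp$sdlog_abundance)))
    copies_rxn <- copies_g * dry_mass /
      (qp$elution_volume_uL / qp$template_volume_uL) / qp$dilution
    cq_true <- g$intercept + g$slope * log10(copies_rxn)
    tidyr::expand_grid(i = seq_len(nrow(samp)), tech_rep = 1:3) |>
      dplyr::mutate(
        sample_id = samp$sample_id[.data$i],
        gene = gene,
        cq = cq_true[.data$i] + rnorm(dplyr::n(), 0, qp$cq_sd),
        true_copies_per_g = copies_g[.data$i]
      ) |>
      dplyr::select(-"i")
  }))
}
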