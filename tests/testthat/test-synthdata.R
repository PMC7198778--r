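test_that("the default scenario encodes the study's design and anchors", {
  sc <- scenario_default()
  expect_equal(nrow(sc$truth), 27L)  # 3 ferts x 3 temps x 3 campaign days
  expect_equal(mean(sc$truth$ratio), 0.62, tolerance = 1e-12)
  expect_equal(range(sc$truth$ratio), c(0.48, 0.75))
  # NPK production responds more strongly to temperature than CT
  q10_of <- function(f, day) {
    tt <- sc$truth[sc$truth$fertilization == f & sc$truth$day == day, ]
    fit_vant_hoff(tt$temperature_C, tt$production)$q10
  }
  expect_gt(q10_of("NPK", 15), q10_of("CT", 15))
  expect_gt(q10_of("NPK", 30), q10_of("CT", 30))
  # MNPK gross rates peak at 25 degC on every campaign day
  for (d in c(3, 15, 30)) {
    tt <- sc$truth[sc$truth$fertilization == "MNPK" & sc$truth$day == d, ]
    expect_equal(tt$temperature_C[which.max(tt$production)], 25)
    expect_equal(tt$temperature_C[which.max(tt$production * tt$ratio)], 25)
  }
  # rates decline along the incubation
  by_day <- aggregate(production ~ day, sc$truth, mean)
  expect_true(all(diff(by_day$production[order(by_day$day)]) < 0))
})

test_that("study generation is deterministic given the seed", {
  sc <- scenario_default()
  a <- generate_study(sc, seed = 5)
  b <- generate_study(sc, seed = 5)
  expect_identical(a, b)
  c <- generate_study(sc, seed = 6)
  expect_false(identical(a$gas, c$gas))
  expect_error(generate_study(sc), "seed")
})

test_that("with no noise and perfect inhibition the pipeline recovers truth exactly", {
  sc <- scenario_default()
  sc$noise_sd <- 0
  sc$replicate_cv <- 0
  st <- generate_study(sc, seed = 2, components = "gas")
  rates <- flux_rates(st$gas)
  est <- partition_rates(rates[rates$day %in% sc$campaign_days, ])
  joined <- dplyr::inner_join(
    est, sc$truth, by = c("fertilization", "temperature_C", "day")
  )
  expect_equal(joined$production.x, joined$production.y, tolerance = 1e-9)
  expect_equal(joined$consumption, joined$production.y * joined$ratio.y,
               tolerance = 1e-9)
  expect_equal(joined$ratio.x, joined$ratio.y, tolerance = 1e-9)
})

test_that("inhibition efficiencies bias the estimators per the closed form", {
  base <- scenario_default()
  base$noise_sd <- 0
  base$replicate_cv <- 0
  est_of <- function(sc) {
    st <- generate_study(sc, seed = 4, components = "gas")
    rates <- flux_rates(st$gas)
    partition_rates(rates[rates$day %in% sc$campaign_days, ]) |>
      dplyr::arrange(.data$fertilization, .data$temperature_C, .data$day)
  }
  full <- est_of(base)

  # partial consumption inhibition lowers both estimators:
  # E[C_hat] = eta_cons * C, E[P_hat] = P - (1 - eta_cons) * C
  part_cons <- base; part_cons$eta_cons <- 0.7
  est_c <- est_of(part_cons)
  expect_equal(est_c$consumption, 0.7 * full$consumption, tolerance = 1e-9)
  expect_equal(est_c$production,
               full$production - 0.3 * full$consumption, tolerance = 1e-9)
  expect_true(all(est_c$consumption < full$consumption))

  # partial nitrification inhibition leaves both estimators unchanged (the
  # nitrification term cancels between the 10 Pa and 10 kPa arms) but
  # attenuates the nitrification-share estimate
  part_nit <- base; part_nit$eta_nit <- 0.5
  est_n <- est_of(part_nit)
  expect_equal(est_n$production, full$production, tolerance = 1e-9)
  expect_equal(est_n$consumption, full$consumption, tolerance = 1e-9)
  share_of <- function(sc) {
    st <- generate_study(sc, seed = 4, components = "gas")
    rates <- flux_rates(st$gas)
    trip <- rates[rates$day == 15 & rates$fertilization == "NPK" &
                    rates$temperature_C == 35, ]
    r0 <- mean(trip$rate_ngN_g_d[trip$c2h2_level == "P0"])
    r10 <- mean(trip$rate_ngN_g_d[trip$c2h2_level == "P10"])
    nitrification_share(r0, r10)$rate
  }
  expect_equal(share_of(part_nit), 0.5 * share_of(base), tolerance = 1e-9)
})

test_that("null studies are flat: true Q10 is 1 and estimates are unbiased", {
  sc <- scenario_null(replicates = 8)
  expect_equal(length(unique(sc$truth$production)), 1L)
  st <- generate_study(sc, seed = 9, components = "gas")
  rates <- flux_rates(st$gas)
  # true rates are temperature-flat: Q10 of the cell-truth equals 1
  f <- fit_vant_hoff(sc$truth$temperature_C,
                     sc$truth$production * (1 - sc$truth$ratio))
  expect_equal(f$q10, 1)
  # estimator is unbiased: the grand mean of estimated production over many
  # replicates approaches the common truth
  est <- partition_rates(rates[rates$day %in% sc$campaign_days, ])
  expect_equal(mean(est$production), 6, tolerance = 0.15)
})

test_that("generated community tables carry the programmed factor contrasts", {
  sc <- scenario_default()
  st <- generate_study(sc, seed = 11, components = "community")
  expect_equal(dplyr::n_distinct(st$peaks_nosZI$sample_id), 120L)
  mat <- process_peaks(st$peaks_nosZI)
  meta <- sample_metadata(rownames(mat))
  keep <- !is.na(meta$temperature_C) & meta$day > 0
  d <- bray_curtis(mat[keep, ])
  meta_k <- meta[keep, ]
  meta_k$fertilization <- factor(meta_k$fertilization)
  meta_k$day <- factor(meta_k$day)
  res <- permanova(d, meta_k, c("day", "fertilization"),
                   permutations = 199, seed = 3)
  # fertilization structures nosZI strongly (the generator's main contrast)
  expect_lt(res$p[res$term == "fertilization"], 0.05)
  expect_gt(res$pseudo_F[res$term == "fertilization"],
            res$pseudo_F[res$term == "day"])
})

test_that("generated qPCR tables round-trip through the quantification stage", {
  sc <- scenario_default()
  st <- generate_study(sc, seed = 13, components = "qpcr")
  curves <- lapply(split(st$standards, st$standards$gene), function(s) {
    fit_standard_curve(s$log10_copies, s$cq)
  })
  expect_equal(curves$nosZI$efficiency, 0.87, tolerance = 0.02)
  expect_equal(curves$nosZII$efficiency, 0.902, tolerance = 0.02)
  ab <- summarise_abundance(st$qpcr, curves,
                            elution_volume_uL = sc$qpcr$elution_volume_uL)
  truth <- dplyr::distinct(st$qpcr, .data$sample_id, .data$gene,
                           .data$true_copies_per_g)
  j <- dplyr::inner_join(ab, truth, by = c("sample_id", "gene"))
  # recovered within the simulated technical noise (on the log scale)
  expect_equal(log10(j$copies_per_g), log10(j$true_copies_per_g),
               tolerance = 0.05)
  # NPK depresses nosZII abundance by an order of magnitude
  m <- dplyr::inner_join(j, sample_metadata(unique(j$sample_id)),
                         by = "sample_id")
  z2 <- m[m$gene == "nosZII", ]
  expect_gt(mean(log10(z2$copies_per_g[z2$fertilization == "CT"])),
            mean(log10(z2$copies_per_g[z2$fertilization == "NPK"])) + 0.5)
})

test_that("emitted CSV tables round-trip through the readers without loss", {
  sc <- scenario_null(replicates = 2, temperatures = c(15, 25),
                      campaign_days = 3)
  st <- generate_study(sc, seed = 21)
  dir <- withr::local_tempdir()
  files <- write_study(st, dir)
  expect_true(all(file.exists(files)))
  gas <- read_gas(file.path(dir, "gas.csv"))
  expect_equal(as.data.frame(gas), as.data.frame(st$gas), tolerance = 1e-12)
  peaks <- read_peaks(file.path(dir, "peaks_nosZI.csv"))
  expect_equal(as.data.frame(peaks), as.data.frame(st$peaks_nosZI))
  expect_error(read_gas(file.path(dir, "nope.csv")), "not found")
})
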