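test_that("standard-curve efficiency reproduces reference slopes", {
  lc <- 3:8
  # perfect doubling: slope -1/log10(2) = -3.3219 -> efficiency 100%
  f_perfect <- fit_standard_curve(lc, 40 - lc / log10(2))
  expect_equal(f_perfect$efficiency, 1, tolerance = 1e-9)
  # the 87.0% efficiency reported for nosZI corresponds to slope -3.679
  f_87 <- fit_standard_curve(lc, 38 - 3.679 * lc)
  expect_equal(f_87$efficiency, 0.870, tolerance = 5e-4)
  expect_equal(f_87$r_squared, 1)
  expect_equal(f_87$slope, -3.679)
})

test_that("efficiency depends on the slope only, not the intercept", {
  lc <- 3:7
  a <- fit_standard_curve(lc, 38 - 3.5 * lc)
  b <- fit_standard_curve(lc, 25 - 3.5 * lc)
  expect_equal(a$efficiency, b$efficiency)
})

test_that("curve fitting guards its preconditions and quality bar", {
  expect_error(fit_standard_curve(1:2, c(30, 27)), ">= 3")
  expect_error(fit_standard_curve(c(3, 3.5, 4), c(30, 29, 28)), "orders of magnitude")
  expect_error(fit_standard_curve(3:6, 10 + 2 * (3:6)), "negative")
  set.seed(2)
  expect_warning(fit_standard_curve(3:8, 38 - 3.5 * (3:8) + rnorm(6, 0, 1.5)),
                 "0.99")
})

test_that("simulate-then-quantify round-trips copy numbers to machine precision", {
  curve <- fit_standard_curve(3:8, 38.2 - 3.58 * (3:8))
  copies_g_true <- 10^seq(5, 9, length.out = 7)
  elution <- 100; dilution <- 20; template <- 2; mass <- 0.5
  copies_rxn <- copies_g_true * mass / (elution / template) / dilution
  cq <- curve$intercept + curve$slope * log10(copies_rxn)
  got <- suppressWarnings(
    quantify(cq, curve, elution_volume_uL = elution, dilution = dilution,
             template_volume_uL = template, extraction_mass_g = mass)
  )
  expect_equal(got, copies_g_true, tolerance = 1e-12)
})

test_that("quantification scales linearly with dilution and handles moisture", {
  curve <- fit_standard_curve(3:8, 38 - 3.5 * (3:8))
  base <- quantify(20, curve, elution_volume_uL = 100, dilution = 10,
                   warn_extrapolation = FALSE)
  expect_equal(quantify(20, curve, elution_volume_uL = 100, dilution = 20,
                        warn_extrapolation = FALSE), 2 * base)
  # 20% moisture: less dry soil in the extraction, more copies per dry gram
  wet <- quantify(20, curve, elution_volume_uL = 100, dilution = 10,
                  moisture = 0.2, warn_extrapolation = FALSE)
  expect_equal(wet, base / 0.8)
  # cq at the intercept corresponds to exactly 1 copy in the reaction
  one_copy <- quantify(curve$intercept, curve, elution_volume_uL = 100,
                       dilution = 1, template_volume_uL = 2,
                       extraction_mass_g = 0.5, warn_extrapolation = FALSE)
  expect_equal(one_copy, 1 * (100 / 2) / 0.5)
  expect_warning(quantify(2, curve, elution_volume_uL = 100), "extrapolation")
  expect_error(quantify(20, curve), "elution")
})

test_that("technical-replicate summaries match hand arithmetic and flag NTCs", {
  curve <- fit_standard_curve(3:8, 38 - 3.5 * (3:8))
  cqs <- c(20.0, 20.1, 19.9)
  qdat <- tibble::tibble(sample_id = "s1", gene = "nosZI", cq = cqs)
  res <- summarise_abundance(qdat, list(nosZI = curve), elution_volume_uL = 100)
  hand <- quantify(cqs, curve, elution_volume_uL = 100,
                   warn_extrapolation = FALSE)
  expect_equal(res$copies_per_g, mean(hand))
  expect_equal(res$cv, sd(hand) / mean(hand))
  expect_false(res$ntc_flag)

  # a late Cq beyond the cutoff is treated as a non-detect and flagged
  qd2 <- tibble::tibble(sample_id = "s2", gene = "nosZI", cq = c(20, 38, NA))
  res2 <- summarise_abundance(qd2, list(nosZI = curve), elution_volume_uL = 100)
  expect_true(res2$ntc_flag)
  expect_equal(res2$n_detect, 1L)
})
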