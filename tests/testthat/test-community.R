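test_that("peak processing applies the length, binning and occurrence rules", {
  peaks <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 4),
    fragment_bp = c(49.6, 50.0, 100.3, 101.8,
                    49.9, 50.2, 100.5, 102.4),
    height = c(10, 20, 30, 40, 10, 25, 35, 45)
  )
  mat <- process_peaks(peaks, occurrence = 0)
  # < 50 bp discarded, boundary closed at exactly 50.0
  expect_false(any(attr(mat, "bins")$seed_bp < 50))
  expect_true(50.0 %in% attr(mat, "bins")$seed_bp)
  # 100.3 and 101.8 share a bin (within 2 bp of the seed); 102.4 does not
  expect_true("TRF_100.3" %in% colnames(mat))
  expect_true("TRF_102.4" %in% colnames(mat))
  expect_equal(mat["s1", "TRF_100.3"], 70 / 90)  # heights summed in-bin
  # relativisation: every row sums to 1
  expect_equal(unname(rowSums(mat)), rep(1, 2))
})

test_that("rare bins are dropped by a strict occurrence threshold", {
  # bin at 200 present in 1 of 10 samples: dropped at 2% (1 <= 0.2... strict)
  peaks <- dplyr::bind_rows(
    tibble::tibble(sample_id = paste0("s", 1:10), fragment_bp = 100, height = 50),
    tibble::tibble(sample_id = "s1", fragment_bp = 200, height = 5)
  )
  m_strict <- process_peaks(peaks, occurrence = 0.1)   # 1 > 1 is FALSE -> drop
  expect_false("TRF_200" %in% colnames(m_strict))
  m_keep <- process_peaks(peaks, occurrence = 0.05)    # 1 > 0.5 -> keep
  expect_true("TRF_200" %in% colnames(m_keep))
})

test_that("samples with no remaining signal are excluded with a warning", {
  peaks <- tibble::tibble(
    sample_id = c("ok", "ok", "empty"),
    fragment_bp = c(100, 150, 30),
    height = c(5, 5, 9)
  )
  expect_warning(mat <- process_peaks(peaks, occurrence = 0), "zero total")
  expect_equal(rownames(mat), "ok")
  expect_equal(attr(mat, "excluded"), "empty")
})

test_that("peak processing is idempotent on an already-processed matrix", {
  set.seed(12)
  raw <- tibble::tibble(
    sample_id = rep(paste0("s", 1:6), each = 8),
    fragment_bp = rep(60 + cumsum(runif(8, 3, 9)), times = 6) +
      runif(48, -0.3, 0.3),
    height = rpois(48, 200)
  )
  m1 <- process_peaks(raw)
  m2 <- process_peaks(community_to_peaks(m1))
  expect_equal(unname(m2[rownames(m1), colnames(m1)]), unname(m1),
               ignore_attr = TRUE)
})

test_that("Bray-Curtis matches hand values and the vegan implementation", {
  expect_equal(bray_curtis(c(1, 2), c(1, 2)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)       # disjoint supports
  expect_equal(bray_curtis(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(-1, 1), c(1, 1)), "non-negative")

  skip_if_not_installed("vegan")
  set.seed(4)
  m <- matrix(runif(30), 5, 6, dimnames = list(paste0("s", 1:5), NULL))
  expect_equal(as.vector(bray_curtis(m)),
               as.vector(vegan::vegdist(m, method = "bray")))
})

test_that("Mantel r and sampled p agree with vegan on the same matrices", {
  skip_if_not_installed("vegan")
  set.seed(6)
  m <- matrix(runif(40), 8, 5)
  x <- as.matrix(dist(m))
  y <- as.matrix(dist(m + matrix(rnorm(40, 0, 0.4), 8, 5)))
  ours <- mantel_test(x, y, permutations = 999, seed = 1)
  ref <- vegan::mantel(x, y, permutations = 999)
  expect_equal(ours$r, unname(ref$statistic))
  # sampled p-values from the two implementations agree within Monte-Carlo error
  expect_lt(abs(ours$p - ref$signif), 0.05)
})

test_that("Mantel p equals the exhaustive-permutation oracle on 4 samples", {
  set.seed(19)
  m1 <- as.matrix(dist(matrix(runif(8), 4, 2)))
  m2 <- as.matrix(dist(matrix(runif(8), 4, 2)))
  res <- mantel_test(m1, m2, exhaustive = TRUE)
  # independent brute force over all 4! relabelings
  r_obs <- oracle_mantel_r(m1, m2, 1:4)
  r_all <- vapply(oracle_perms(4L), function(p) oracle_mantel_r(m1, m2, p),
                  numeric(1))
  expect_equal(res$r, r_obs)
  expect_equal(res$p, mean(r_all >= r_obs - 1e-12))
  expect_equal(res$permutations, 24L)
})

test_that("sampled Mantel p converges to the exhaustive p", {
  set.seed(23)
  m1 <- as.matrix(dist(matrix(runif(12), 6, 2)))
  m2 <- as.matrix(dist(matrix(runif(12), 6, 2)))
  exact <- mantel_test(m1, m2, exhaustive = TRUE)$p
  sampled <- mantel_test(m1, m2, permutations = 19999, seed = 2)$p
  expect_lt(abs(sampled - exact), 0.02)
})

test_that("Mantel errors on constant distances and identical-matrix r is 1", {
  m <- as.matrix(dist(matrix(runif(10), 5, 2)))
  expect_equal(mantel_test(m, m, permutations = 99, seed = 1)$r, 1)
  konst <- matrix(1, 5, 5); diag(konst) <- 0
  expect_error(mantel_test(m, konst, permutations = 99), "constant")
})

test_that("PERMANOVA pseudo-F equals a direct SS decomposition on 6 samples", {
  # one factor, two groups of three; hand-computable from squared distances
  x <- c(1.0, 1.3, 0.8, 4.0, 4.4, 3.7)
  g <- rep(c("lo", "hi"), each = 3)
  d <- as.matrix(dist(x))
  res <- permanova(d, data.frame(g = g), "g", permutations = 199, seed = 1)
  # direct arithmetic oracle: SS_total = sum d^2 / n; SS_within from
  # within-group pairs; pseudo-F = (SS_A/1) / (SS_W/4)
  n <- 6
  ss_total <- sum(d[lower.tri(d)]^2) / n
  ss_within <- sum((d[1:3, 1:3])[lower.tri(d[1:3, 1:3])]^2) / 3 +
    sum((d[4:6, 4:6])[lower.tri(d[4:6, 4:6])]^2) / 3
  ss_among <- ss_total - ss_within
  f_oracle <- (ss_among / 1) / (ss_within / 4)
  expect_equal(res$pseudo_F[1], f_oracle)
  expect_equal(res$SS[res$term == "Total"], ss_total)
})

test_that("PERMANOVA on univariate Euclidean data collapses to the ANOVA F", {
  set.seed(33)
  y <- rnorm(15, rep(c(0, 1, 3), each = 5))
  g <- factor(rep(c("a", "b", "c"), each = 5))
  res <- permanova(dist(y), data.frame(g = g), "g", permutations = 199, seed = 2)
  f_classic <- anova(lm(y ~ g))$`F value`[1]
  expect_equal(res$pseudo_F[1], f_classic)
})

test_that("PERMANOVA matches vegan::adonis2 for sequential crossed factors", {
  skip_if_not_installed("vegan")
  set.seed(44)
  meta <- tidyr::expand_grid(f1 = c("x", "y"), f2 = c("p", "q", "r"),
                             rep = 1:3)
  m <- matrix(rexp(nrow(meta) * 8), nrow(meta), 8) +
    2 * (meta$f1 == "x") + outer(as.integer(factor(meta$f2)), rep(1, 8))
  d <- vegan::vegdist(m, "bray")
  ours <- permanova(d, as.data.frame(meta), c("f1", "f2", "f1:f2"),
                    permutations = 499, seed = 5)
  ref <- vegan::adonis2(d ~ f1 + f2 + f1:f2, data = as.data.frame(meta),
                        permutations = 499, by = "terms")
  expect_equal(ours$SS[1:3], ref$SumOfSqs[1:3], tolerance = 1e-10)
  expect_equal(ours$pseudo_F[1:3], ref$F[1:3], tolerance = 1e-10)
  expect_equal(ours$df[1:3], ref$Df[1:3])
})

test_that("PERMANOVA is invariant to relabeling and guards degenerate designs", {
  set.seed(55)
  y <- matrix(runif(24), 8, 3)
  d <- dist(y)
  g <- rep(c("a", "b"), each = 4)
  f1 <- permanova(d, data.frame(g = g), "g", permutations = 99, seed = 1)
  g2 <- ifelse(g == "a", "B", "A")  # identical partition, new labels
  f2 <- permanova(d, data.frame(g = g2), "g", permutations = 99, seed = 1)
  expect_equal(f1$pseudo_F[1], f2$pseudo_F[1])
  expect_error(permanova(d, data.frame(g = as.character(1:8)), "g",
                         permutations = 99), "residual degrees")
  expect_error(permanova(d, data.frame(g = rep("a", 8)), "g",
                         permutations = 99), "levels")
})

test_that("rate correlations reproduce closed-form cases", {
  x <- c(1, 2, 3, 4, 5)
  res <- correlate_rates(x, 2 * x)
  expect_equal(res$r, 1)
  expect_equal(res$slope, 2)
  expect_lt(res$p, 1e-6)
  expect_error(correlate_rates(x, rep(3, 5)), "zero variance")
  expect_error(correlate_rates(1:2, 1:2), ">= 3")

  # under independence |r| concentrates near 0
  set.seed(66)
  rs <- replicate(500, correlate_rates(rnorm(9), rnorm(9))$r)
  expect_lt(abs(median(rs)), 0.1)
})

test_that("principal-coordinates projection preserves Euclidean configurations", {
  set.seed(70)
  y <- matrix(rnorm(12), 6, 2)
  rownames(y) <- paste0("s", 1:6)
  sc <- ordinate_pcoa(dist(y), k = 2)
  expect_equal(as.vector(dist(as.matrix(sc[, c("PCo1", "PCo2")]))),
               as.vector(dist(y)), tolerance = 1e-8)
})
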