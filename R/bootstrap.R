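#' Bootstrap + Monte-Carlo inference for gross process rates
#'
#' The gross production estimate is the consumption estimate plus the net
#' rate, so the two estimators share sampling error by construction. To keep
#' that correlation from distorting naive standard errors, uncertainty is
#' quantified by a case bootstrap over replicate triplets combined with
#' Monte-Carlo measurement noise: each draw resamples the replicate triplets
#' with replacement within every cell, perturbs each member rate with
#' independent Gaussian noise of standard deviation `mc_sd`, and recomputes
#' the statistic. Percentile intervals and bootstrap two-sided p-values for
#' pairwise temperature comparisons (within fertilization x day) are
#' returned; `p = 2 * min(P(diff > 0), P(diff < 0))` with an add-one
#' correction and capped at 1.
#'
#' @inheritParams partition_rates
#' @param statistic Cell-level statistic to track: `"gross_production"`,
#'   `"gross_consumption"`, `"net"` or `"ratio"`.
#' @param B Number of bootstrap draws (>= 200).
#' @param mc_sd Standard deviation of the additive Monte-Carlo measurement
#'   noise, in rate units (0 disables the noise layer).
#' @param seed Optional integer seed; with a fixed seed the result is
#'   reproducible bit for bit.
#' @param alpha Two-sided interval level (default 0.05 for 95% CIs).
#' @param p_adjust Multiplicity rule for the pairwise comparisons:
#'   `"none"` (per-comparison, default) or `"holm"`.
#' @param keep_draws Keep the per-draw cell statistics (production,
#'   consumption, net, ratio arrays) in the result.
#' @return An object of class `n2o_bootstrap`: point estimates with
#'   percentile CIs per cell, a pairwise temperature comparison table, and
#'   the configuration (B, mc_sd, seed, alpha).
#' @export
bootstrap_partition <- function(rates,
                                statistic = c("gross_production",
                                              "gross_consumption",
                                              "net", "ratio"),
                                B = 1000, mc_sd = 0, seed = NULL,
                                alpha = 0.05,
                                p_adjust = c("none", "holm"),
                                keep_draws = FALSE) {
  statistic <- match.arg(statistic)
  p_adjust <- match.arg(p_adjust)
  if (B < 200) stop("B must be >= 200 for stable percentile intervals", call. = FALSE)
  trip <- triplet_table(rates)
  cell_id <- paste(trip$fertilization, trip$temperature_C, trip$day, sep = "/")
  cells <- unique(cell_id)
  idx_by_cell <- split(seq_len(nrow(trip)), factor(cell_id, levels = cells))
  n_by_cell <- lengths(idx_by_cell)
  if (any(n_by_cell == 1L) && mc_sd == 0) {
    stop("degenerate cell(s) with a single replicate and mc_sd = 0: ",
         "the bootstrap distribution would collapse", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  cell_f <- factor(cell_id, levels = cells)
  nr <- nrow(trip)
  stat_one <- function(r0, r10, r10k) {
    con <- r10k - r10
    pro <- con + r0
    m_pro <- as.numeric(rowsum(pro, cell_f)) / n_by_cell
    m_con <- as.numeric(rowsum(con, cell_f)) / n_by_cell
    m_net <- as.numeric(rowsum(r0, cell_f)) / n_by_cell
    cbind(production = m_pro, consumption = m_con, net = m_net,
          ratio = ifelse(m_pro > 0, m_con / m_pro, NA_real_))
  }

  point <- stat_one(trip$r0, trip$r10, trip$r10k)
  draws <- array(NA_real_, c(length(cells), 4L, B),
                 dimnames = list(cells, colnames(point), NULL))
  for (b in seq_len(B)) {
    take <- unlist(lapply(idx_by_cell, function(ix) {
      ix[sample.int(length(ix), length(ix), replace = TRUE)]
    }), use.names = FALSE)
    noise <- if (mc_sd > 0) matrix(rnorm(3L * nr, 0, mc_sd), nr, 3L) else matrix(0, nr, 3L)
    draws[, , b] <- stat_one(trip$r0[take] + noise[, 1L],
                             trip$r10[take] + noise[, 2L],
                             trip$r10k[take] + noise[, 3L])
  }

  stat_col <- switch(statistic, gross_production = "production",
                     gross_consumption = "consumption", net = "net",
                     ratio = "ratio")
  stat_draws <- draws[, stat_col, , drop = TRUE]
  if (is.null(dim(stat_draws))) stat_draws <- matrix(stat_draws, nrow = 1L)

  ci <- t(apply(stat_draws, 1L, quantile,
                probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  key <- do.call(rbind, strsplit(cells, "/", fixed = TRUE))
  estimates <- tibble::tibble(
    fertilization = key[, 1L],
    temperature_C = as.numeric(key[, 2L]),
    day = as.numeric(key[, 3L]),
    n = as.integer(n_by_cell),
    point = point[, stat_col],
    lower = ci[, 1L],
    upper = ci[, 2L]
  )
  bad_ci <- B >= 1000 &
    (estimates$point < estimates$lower | estimates$point > estimates$upper)
  if (any(bad_ci)) {
    warning("percentile CI does not bracket the point estimate in ",
            sum(bad_ci), " cell(s)", call. = FALSE)
  }

  comparisons <- boot_pairwise_temps(estimates, stat_draws, B)
  comparisons$p_adj <- if (p_adjust == "holm") {
    p.adjust(comparisons$p, method = "holm")
  } else {
    comparisons$p
  }

  structure(
    list(statistic = statistic, B = B, mc_sd = mc_sd, seed = seed,
         alpha = alpha, estimates = estimates, comparisons = comparisons,
         draws = if (keep_draws) draws else NULL),
    class = "n2o_bootstrap"
  )
}

# Pairwise temperature contrasts within fertilization x day from the
# bootstrap draws of the tracked statistic.
boot_pairwise_temps <- function(estimates, stat_draws, B) {
  out <- list()
  groups <- unique(estimates[c("fertilization", "day")])
  for (g in seq_len(nrow(groups))) {
    rows <- which(estimates$fertilization == groups$fertilization[g] &
                    estimates$day == groups$day[g])
    temps <- estimates$temperature_C[rows]
    if (length(rows) < 2L) next
    prs <- utils::combn(seq_along(rows), 2L)
    for (k in seq_len(ncol(prs))) {
      i <- rows[prs[1L, k]]; j <- rows[prs[2L, k]]
      d <- stat_draws[i, ] - stat_draws[j, ]
      d <- d[!is.na(d)]
      nb <- length(d)
      p <- if (nb == 0L) NA_real_ else {
        min(1, 2 * min((1 + sum(d <= 0)) / (nb + 1), (1 + sum(d >= 0)) / (nb + 1)))
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        fertilization = groups$fertilization[g], day = groups$day[g],
        temperature_A = temps[prs[1L, k]], temperature_B = temps[prs[2L, k]],
        difference = estimates$point[i] - estimates$point[j],
        lower = quantile(d, 0.025, names = FALSE),
        upper = quantile(d, 0.975, names = FALSE),
        p = p
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(
      fertilization = character(), day = numeric(),
      temperature_A = numeric(), temperature_B = numeric(),
      difference = numeric(), lower = numeric(), upper = numeric(),
      p = numeric()
    ))
  }
  dplyr::bind_rows(out)
}

#' @export
print.n2o_bootstrap <- function(x, ...) {
  cat("Bootstrap + Monte-Carlo inference (", x$statistic, ")\n", sep = "")
  cat("  B = ", x$B, ", mc_sd = ", x$mc_sd,
      if (!is.null(x$seed)) paste0(", seed = ", x$seed), "\n", sep = "")
  print(x$estimates, ...)
  invisible(x)
}
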