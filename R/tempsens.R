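#' Fit a van't Hoff temperature-response curve and compute Q10
#'
#' Fits `R = alpha * exp(beta * t)` to (cumulative) emissions measured at two
#' or more temperatures and reports `Q10 = exp(10 * beta)`, the factor by
#' which the rate increases per 10 degC warming. The default fit is ordinary
#' least squares of `log(R)` on `t`, which is exact whenever the points lie
#' on a true exponential; a nonlinear least-squares fit on the raw scale is
#' available via `method = "nls"` (initialised from the log fit).
#'
#' @param temperature_C Incubation temperatures (degC).
#' @param emission Emissions or rates, all strictly positive.
#' @param method `"log-ols"` (default) or `"nls"`.
#' @return An object of class `q10_fit` with elements `alpha`, `beta`,
#'   `q10`, `r_squared` (on the log scale), `n` and `method`.
#' @export
#' @examples
#' fit_vant_hoff(c(15, 25, 35), c(100, 200, 400))$q10 # exactly 2
fit_vant_hoff <- function(temperature_C, emission,
                          method = c("log-ols", "nls")) {
  method <- match.arg(method)
  if (length(temperature_C) != length(emission)) {
    stop("`temperature_C` and `emission` lengths differ", call. = FALSE)
  }
  if (length(emission) < 2L) {
    stop("need at least 2 temperature points", call. = FALSE)
  }
  if (any(!is.finite(emission)) || any(emission <= 0)) {
    stop("all emissions must be positive for the van't Hoff log fit; ",
         "non-positive values cannot be log-transformed (consider whether ",
         "an offset is scientifically defensible before re-fitting)",
         call. = FALSE)
  }
  if (length(emission) == 2L) {
    warning("2-point fit is exact with zero residual degrees of freedom",
            call. = FALSE)
  }
  fit <- lm(log(emission) ~ temperature_C)
  beta <- unname(coef(fit)[2L])
  alpha <- exp(unname(coef(fit)[1L]))
  ss_tot <- sum((log(emission) - mean(log(emission)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  if (method == "nls") {
    # scaleOffset keeps the convergence test defined on zero-residual data
    nl <- stats::nls(emission ~ a * exp(b * temperature_C),
                     start = list(a = alpha, b = beta),
                     control = stats::nls.control(maxiter = 200,
                                                  scaleOffset = 1))
    alpha <- unname(coef(nl)["a"])
    beta <- unname(coef(nl)["b"])
  }
  structure(
    list(alpha = alpha, beta = beta, q10 = exp(10 * beta),
         r_squared = r2, n = length(emission), method = method),
    class = "q10_fit"
  )
}

#' @export
print.q10_fit <- function(x, ...) {
  cat(sprintf(
    "van't Hoff fit (%s, n = %d): alpha = %.4g, beta = %.4f per degC, Q10 = %.3f (R2 = %.3f)\n",
    x$method, x$n, x$alpha, x$beta, x$q10, x$r_squared
  ))
  invisible(x)
}

#' Per-replicate and pooled Q10 for grouped emission series
#'
#' @param data A tibble with columns `temperature_C`, `replicate` and an
#'   emission column.
#' @param emission Name of the emission column (default
#'   `"cumulative_ngN_g"`).
#' @return A list with `pooled` (a [fit_vant_hoff()] object over all points)
#'   and `per_replicate`, a tibble of replicate-wise `beta` and `q10`.
#' @export
q10_by_replicate <- function(data, emission = "cumulative_ngN_g") {
  stopifnot(all(c("temperature_C", "replicate", emission) %in% names(data)))
  per <- data |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_vant_hoff(d$temperature_C, d[[emission]])
      tibble::tibble(beta = f$beta, q10 = f$q10)
    }) |>
    dplyr::ungroup()
  list(
    pooled = fit_vant_hoff(data$temperature_C, data[[emission]]),
    per_replicate = per
  )
}

#' Compare Q10 between two treatment groups by replicate bootstrap
#'
#' Fits a van't Hoff curve per replicate in each group, then bootstraps the
#' replicates within groups to obtain a percentile CI for the Q10 difference
#' (group A minus group B) and a two-sided bootstrap p-value,
#' `p = 2 * min(P(diff > 0), P(diff < 0))` with an add-one correction.
#'
#' @param group_a,group_b Tibbles with columns `temperature_C`, `replicate`
#'   and the emission column, one series per replicate.
#' @param emission Name of the emission column.
#' @param B Bootstrap draws.
#' @param seed Optional integer seed for reproducibility.
#' @param alpha Interval level (default 95% CI).
#' @return A list with the observed per-group Q10 (mean of per-replicate
#'   Q10s), their `difference`, percentile `lower`/`upper`, and `p`.
#' @export
compare_q10 <- function(group_a, group_b, emission = "cumulative_ngN_g",
                        B = 1000, seed = NULL, alpha = 0.05) {
  qa <- q10_by_replicate(group_a, emission)$per_replicate$q10
  qb <- q10_by_replicate(group_b, emission)$per_replicate$q10
  if (length(qa) < 2L || length(qb) < 2L) {
    stop("need >= 2 replicate series per group", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- vapply(seq_len(B), function(b) {
    mean(sample(qa, replace = TRUE)) - mean(sample(qb, replace = TRUE))
  }, numeric(1))
  p <- min(1, 2 * min((1 + sum(d <= 0)) / (B + 1), (1 + sum(d >= 0)) / (B + 1)))
  list(
    q10_a = mean(qa), q10_b = mean(qb), difference = mean(qa) - mean(qb),
    lower = quantile(d, alpha / 2, names = FALSE),
    upper = quantile(d, 1 - alpha / 2, names = FALSE),
    p = p, B = B, seed = seed
  )
}
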