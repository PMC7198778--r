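#' Process T-RFLP peak tables into a relative-abundance community matrix
#'
#' Applies the standard T-RFLP cleaning rules: discard fragments shorter
#' than `min_len` (primer-dimer noise; the boundary is closed, 50.0 bp is
#' kept), align fragments across samples by single-pass binning (a bin is
#' seeded at the smallest unassigned fragment length and collects every
#' fragment within `[seed, seed + bin_width)`), sum peak heights within each
#' sample x bin, drop rare bins present in no more than
#' `occurrence * n_samples` samples (strict inequality), and relativise peak
#' heights within samples so every row sums to 1.
#'
#' @param peaks A tibble with columns `sample_id`, `fragment_bp` (decimal
#'   base pairs) and `height` (fluorescence units, >= 0).
#' @param min_len Minimum fragment length retained (bp).
#' @param bin_width Binning window (bp).
#' @param occurrence Rare-bin threshold as a fraction of the total number of
#'   samples.
#' @param min_height Optional noise floor: peaks below it are discarded
#'   before binning (default 0 = off).
#' @return A numeric matrix (samples x bins, columns `TRF_<seed length>`)
#'   whose rows sum to 1, with attributes `bins` (tibble of bin seeds) and
#'   `excluded` (samples dropped for zero total height).
#' @export
process_peaks <- function(peaks, min_len = 50, bin_width = 2,
                          occurrence = 0.02, min_height = 0) {
  stopifnot(all(c("sample_id", "fragment_bp", "height") %in% names(peaks)))
  if (bin_width <= 0 || min_len <= 0) {
    stop("`min_len` and `bin_width` must be positive", call. = FALSE)
  }
  samples <- unique(peaks$sample_id)
  n_total <- length(samples)
  if (n_total < 1L) stop("no samples in peak table", call. = FALSE)

  keep <- peaks$fragment_bp >= min_len & peaks$height > min_height
  peaks <- peaks[keep, , drop = FALSE]

  lens <- sort(unique(peaks$fragment_bp))
  if (length(lens) == 0L) stop("no peaks left after length filtering", call. = FALSE)
  seeds <- numeric(0)
  current <- -Inf
  for (l in lens) {
    if (l - current >= bin_width) {
      seeds <- c(seeds, l)
      current <- l
    }
  }
  bin_of <- seeds[findInterval(peaks$fragment_bp, seeds)]

  mat <- matrix(0, n_total, length(seeds),
                dimnames = list(samples, paste0("TRF_", seeds)))
  agg <- rowsum(peaks$height,
                group = paste(peaks$sample_id, bin_of, sep = "\r"))
  key <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  mat[cbind(key[, 1L], paste0("TRF_", key[, 2L]))] <- agg[, 1L]

  presence <- colSums(mat > 0)
  mat <- mat[, presence > occurrence * n_total, drop = FALSE]

  totals <- rowSums(mat)
  excluded <- rownames(mat)[totals == 0]
  if (length(excluded)) {
    warning("excluding sample(s) with zero total height after filtering: ",
            paste(excluded, collapse = ", "), call. = FALSE)
    mat <- mat[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  mat <- mat / totals
  attr(mat, "bins") <- tibble::tibble(
    bin = colnames(mat),
    seed_bp = as.numeric(sub("^TRF_", "", colnames(mat)))
  )
  attr(mat, "excluded") <- excluded
  mat
}

#' Flatten a community matrix back to a long peak table
#'
#' Inverse of [process_peaks()] up to the lost within-bin detail: each bin
#' becomes a single peak at its seed length. Useful for round-trips and for
#' writing `peaks.csv` files.
#'
#' @param mat A community matrix with a `bins` attribute (or numeric
#'   column names parseable from `TRF_<length>`).
#' @return A tibble with `sample_id`, `fragment_bp`, `height`.
#' @export
community_to_peaks <- function(mat) {
  lens <- as.numeric(sub("^TRF_", "", colnames(mat)))
  out <- tibble::tibble(
    sample_id = rep(rownames(mat), times = ncol(mat)),
    fragment_bp = rep(lens, each = nrow(mat)),
    height = as.vector(mat)
  )
  out[out$height > 0, , drop = FALSE]
}

#' Bray-Curtis dissimilarity
#'
#' `sum(|x - y|) / sum(x + y)`, in `[0, 1]` for non-negative inputs. Given a
#' matrix, returns the full pairwise `dist`. Bray-Curtis is not metric (the
#' triangle inequality can fail); no metricity is assumed downstream.
#'
#' @param x Non-negative abundance vector, or a samples x taxa matrix.
#' @param y Second vector when `x` is a vector.
#' @return A single dissimilarity, or a `dist` object for matrix input.
#' @export
#' @examples
#' bray_curtis(c(0.5, 0.5), c(1, 0)) # 0.5
bray_curtis <- function(x, y = NULL) {
  if (is.matrix(x) || is.data.frame(x)) {
    m <- as.matrix(x)
    if (any(m < 0)) stop("abundances must be non-negative", call. = FALSE)
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- bray_curtis(m[i, ], m[j, ])
      }
    }
    return(stats::as.dist(d))
  }
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative", call. = FALSE)
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("Bray-Curtis undefined for two all-zero vectors", call. = FALSE)
  sum(abs(x - y)) / tot
}

# All permutations of 1..n as a matrix (n! rows); guarded for small n.
all_permutations <- function(n) {
  if (n > 7L) stop("exhaustive enumeration limited to n <= 7", call. = FALSE)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower triangles, with significance from joint
#' row/column permutation of the second matrix. The sampled p-value is
#' `(1 + #(r_perm >= r_obs)) / (permutations + 1)` for the default one-sided
#' (positive association) alternative; `exhaustive = TRUE` enumerates all
#' `n!` relabelings (n <= 7) and returns the exact permutation p-value.
#'
#' @param d1,d2 `dist` objects or square symmetric matrices over the same
#'   samples in the same order.
#' @param permutations Number of sampled permutations (>= 99).
#' @param seed Optional integer seed.
#' @param alternative `"greater"` (default, positive association) or
#'   `"two.sided"`.
#' @param exhaustive Enumerate all permutations instead of sampling.
#' @return A list with `r`, `p`, `permutations`, `alternative`, `seed`.
#' @export
mantel_test <- function(d1, d2, permutations = 9999, seed = NULL,
                        alternative = c("greater", "two.sided"),
                        exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) stop("distance matrices differ in size", call. = FALSE)
  n <- nrow(m1)
  low <- lower.tri(m1)
  v1 <- m1[low]
  if (sd(v1) == 0 || sd(m2[low]) == 0) {
    stop("constant distance vector: Mantel r undefined", call. = FALSE)
  }
  r_of <- function(perm) {
    v2 <- m2[perm, perm][low]
    if (sd(v2) == 0) return(NA_real_)
    cor(v1, v2)
  }
  r_obs <- r_of(seq_len(n))
  score <- function(r) if (alternative == "greater") r else abs(r)
  if (exhaustive) {
    perms <- all_permutations(n)
    r_all <- apply(perms, 1L, r_of)
    p <- mean(score(r_all) >= score(r_obs) - 1e-12, na.rm = TRUE)
    n_perm <- nrow(perms)
  } else {
    if (permutations < 99) stop("use at least 99 permutations", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    r_perm <- vapply(seq_len(permutations),
                     function(i) r_of(sample.int(n)), numeric(1))
    p <- (1 + sum(score(r_perm) >= score(r_obs) - 1e-12, na.rm = TRUE)) /
      (permutations + 1)
    n_perm <- permutations
  }
  list(r = r_obs, p = p, permutations = n_perm,
       alternative = alternative, exhaustive = exhaustive, seed = seed)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squared dissimilarities among sequential
#' model terms following the Gower-centred inner-product formulation: with
#' `G` the doubly centred matrix of `-d^2/2`, the sum of squares explained
#' by a term is the increment in `tr(H G)` as the term's columns join the
#' design, and `pseudo-F = (SS_term / df_term) / (SS_residual /
#' df_residual)`. Significance is assessed by free permutation of the sample
#' labels, recomputing every term's pseudo-F.
#'
#' @param d A `dist` or square symmetric dissimilarity matrix.
#' @param data A data frame of sample metadata, rows matching `d`'s order.
#' @param terms Character vector of sequential model terms, e.g.
#'   `c("day", "fertilization", "day:fertilization")`.
#' @param permutations Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return A tibble with one row per term: `df`, `SS`, `R2`, `pseudo_F`,
#'   `p`, plus residual and total rows.
#' @export
permanova <- function(d, data, terms, permutations = 10000, seed = NULL) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (nrow(data) != n) stop("metadata rows must match the distance matrix", call. = FALSE)
  base_vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  for (v in base_vars) {
    if (!v %in% names(data)) stop("metadata lacks variable `", v, "`", call. = FALSE)
    if (length(unique(data[[v]])) < 2L) {
      stop("factor `", v, "` needs >= 2 levels", call. = FALSE)
    }
    if (!is.numeric(data[[v]])) data[[v]] <- factor(data[[v]])
  }
  A <- -0.5 * m^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J

  hats <- vector("list", length(terms))
  ranks <- integer(length(terms))
  for (k in seq_along(terms)) {
    X <- model.matrix(stats::reformulate(terms[seq_len(k)]), data)
    qr_x <- qr(X)
    Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
    hats[[k]] <- tcrossprod(Q)
    ranks[k] <- qr_x$rank
  }
  df_terms <- diff(c(1L, ranks))
  df_res <- n - ranks[length(ranks)]
  if (df_res <= 0) {
    stop("zero residual degrees of freedom (one sample per cell?)", call. = FALSE)
  }

  ss_of <- function(Gp) {
    tr_seq <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    ss_total <- sum(diag(Gp))
    ss_terms <- diff(c(0, tr_seq))
    ss_res <- ss_total - tr_seq[length(tr_seq)]
    list(terms = ss_terms, res = ss_res, total = ss_total)
  }
  obs <- ss_of(G)
  f_obs <- (obs$terms / df_terms) / (obs$res / df_res)

  if (!is.null(seed)) set.seed(seed)
  exceed <- numeric(length(terms))
  for (i in seq_len(permutations)) {
    p <- sample.int(n)
    ssp <- ss_of(G[p, p])
    f_p <- (ssp$terms / df_terms) / (ssp$res / df_res)
    exceed <- exceed + (f_p >= f_obs - 1e-12)
  }
  p_vals <- (1 + exceed) / (permutations + 1)

  tibble::tibble(
    term = c(terms, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1L),
    SS = c(obs$terms, obs$res, obs$total),
    R2 = c(obs$terms, obs$res, obs$total) / obs$total,
    pseudo_F = c(f_obs, NA, NA),
    p = c(p_vals, NA, NA)
  )
}

#' Pearson correlation between paired cell-level series
#'
#' Standard correlation with a two-sided t-test and a linear fit with 95%
#' confidence limits; used for rate-vs-rate and abundance-vs-rate relations.
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @param conf Confidence level for the linear-fit slope interval.
#' @return A list with `r`, `p`, `n`, `slope`, `intercept`,
#'   `slope_ci` (length-2).
#' @export
correlate_rates <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 paired observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in input", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  # zero-residual fits give a zero-width interval; the summary.lm warning
  # about perfect fits is expected there
  ci <- suppressWarnings(stats::confint(fit, "x", level = conf))
  list(
    r = unname(ct$estimate), p = ct$p.value, n = length(x),
    slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
    slope_ci = as.numeric(ci)
  )
}

#' Principal-coordinates projection of a dissimilarity matrix
#'
#' Thin wrapper over classical multidimensional scaling
#' ([stats::cmdscale()]), provided for plotting community ordinations; no
#' numeric results are consumed downstream.
#'
#' @param d A `dist` or square symmetric matrix.
#' @param k Number of axes.
#' @return A tibble of sample scores with `sample_id` and `PCo1..PCok`.
#' @export
ordinate_pcoa <- function(d, k = 2) {
  sc <- cmdscale(as.matrix(d), k = k)
  colnames(sc) <- paste0("PCo", seq_len(k))
  tibble::as_tibble(sc, rownames = "sample_id")
}
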