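# Build a long rates table for one or more cells from per-replicate triplets.
make_rates <- function(r0, r10, r10k, fertilization = "CT",
                       temperature_C = 25, day = 3) {
  n <- length(r0)
  tibble::tibble(
    fertilization = fertilization,
    temperature_C = temperature_C,
    day = day,
    replicate = rep(seq_len(n), 3L),
    c2h2_level = rep(c("P0", "P10", "KP10"), each = n),
    rate_ngN_g_d = c(r0, r10, r10k)
  )
}

# Draw a null rates table: every cell shares the same true production /
# consumption; replicate effects are lognormal and shared across the
# triplet of a replicate, measurement noise is additive Gaussian.
draw_null_rates <- function(n = 12, cv = 0.4, noise_sd = 0.25,
                            temperatures = c(15, 25), production = 6,
                            ratio = 0.5) {
  sdl <- sqrt(log(1 + cv^2))
  dplyr::bind_rows(lapply(temperatures, function(temp) {
    L <- exp(rnorm(n, -sdl^2 / 2, sdl))
    P <- production * L
    C <- ratio * production * L
    make_rates(
      r0 = P - C + rnorm(n, 0, noise_sd),
      r10 = P - C + rnorm(n, 0, noise_sd),
      r10k = P + rnorm(n, 0, noise_sd),
      temperature_C = temp
    )
  }))
}

# Independent recursive enumeration of all permutations of 1..n (test-side
# oracle, deliberately separate from the package's implementation).
oracle_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Oracle Mantel r for a permutation of the second matrix.
oracle_mantel_r <- function(m1, m2, perm) {
  low <- lower.tri(m1)
  cor(m1[low], m2[perm, perm][low])
}
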