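# Shared fixtures and independent oracles.

# A well-separated variant of the default mixture: per-phenotype means pushed
# apart (deviations from the size-weighted grand mean doubled) and
# within-phenotype SDs shrunk fifteen-fold, so every indicator separates the
# groups even after per-column IQR scaling. Used for separability/stability
# properties whose premise is "clusters are well separated" (the default
# spec's overlapping groups test the opposite regime).
separated_spec <- function(seed = 1L, group_sizes = c(60L, 80L, 160L),
                           separation = 2, shrink = 15) {
  spec <- default_spec(seed = seed)
  w <- spec$weights
  for (ind in unique(spec$params$indicator)) {
    sel <- spec$params$indicator == ind
    m <- spec$params$mean[sel]
    grand <- sum(w * m)
    spec$params$mean[sel] <- grand + separation * (m - grand)
  }
  spec$params$sd <- spec$params$sd / shrink
  synth_spec(group_sizes = group_sizes, params = spec$params,
             missing_rate = 0, outlier_rate = 0, seed = seed)
}

# small random cohort table over a subset of the registry
random_cohort <- function(n = 10, miss = 0.1, seed = 1) {
  set.seed(seed)
  reg <- default_registry()
  reg <- reg[reg$kind == "base", ]
  v <- matrix(abs(rnorm(n * nrow(reg), 10, 3)), n, nrow(reg))
  if (n > 0 && miss > 0) v[matrix(runif(length(v)) < miss, n)] <- NA
  cohort_table(v, reg)
}

# brute-force minimal-inertia partition: all assignments of n points to k
# groups (every cluster may be empty except the best solution never is when
# beneficial); exact for n <= 8, k <= 3
brute_force_inertia <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- as.integer(grid[r, ])
    if (length(unique(lab)) < k) next
    w <- 0
    for (g in unique(lab)) {
      xi <- x[lab == g, , drop = FALSE]
      w <- w + sum(sweep(xi, 2, colMeans(xi))^2)
    }
    if (w < best) best <- w
  }
  best
}

# pair-enumeration Rand / adjusted Rand oracles
pair_rand_oracle <- function(a, b) {
  n <- length(a)
  agree <- 0; tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a == same_b) agree <- agree + 1
  }
  agree / tot
}

pair_ari_oracle <- function(a, b) {
  # expectation-adjusted from pair counts
  n <- length(a)
  ss <- 0; sa <- 0; sb <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a && same_b) ss <- ss + 1
    if (same_a) sa <- sa + 1
    if (same_b) sb <- sb + 1
  }
  n2 <- choose(n, 2)
  expected <- sa * sb / n2
  maxidx <- (sa + sb) / 2
  if (abs(maxidx - expected) < 1e-12) return(1)
  (ss - expected) / (maxidx - expected)
}

# inverse Yeo-Johnson (for lambda-recovery tests)
yj_inverse <- function(z, lambda) {
  out <- z
  pos <- z >= 0; neg <- !pos
  if (abs(lambda) > 1e-10) {
    out[pos] <- (z[pos] * lambda + 1)^(1 / lambda) - 1
  } else out[pos] <- expm1(z[pos])
  if (abs(lambda - 2) > 1e-10) {
    out[neg] <- 1 - (-(2 - lambda) * z[neg] + 1)^(1 / (2 - lambda))
  } else out[neg] <- -expm1(-z[neg])
  out
}
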