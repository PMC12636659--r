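#' Synthetic hemodialysis cohorts
#'
#' The generator emulates a three-phenotype maintenance-hemodialysis cohort:
#' a finite mixture over the 17 base indicators whose per-phenotype means and
#' SDs equal published phenotype summary statistics (group sizes
#' 236/294/677, n = 1,207). Right-skewed laboratory variables (CRP,
#' ferritin, iPTH, ALP, WBC, pre-dialysis beta2-microglobulin, TSAT) are
#' moment-matched lognormals; the beta2-microglobulin reduction ratio is a
#' truncated normal on \[0, 100\]; electrolyte deltas are truncated normals
#' at 0; the remaining variables are Gaussian. Composite indicators are
#' never sampled -- they are derived with [derive_all()], so generated
#' tables can never be internally inconsistent.
#'
#' @name synthetic
NULL

# per-phenotype mean/SD for the 17 base indicators; columns:
# m0,s0 = high retention-inflammatory, m1,s1 = optimal clearance,
# m2,s2 = intermediate-stable
.PHENOTYPE_PARAMS <- local({
  x <- rbind(
    wbc        = c(6.21, 1.78,  5.84, 1.71,  6.17, 1.98),
    crp        = c(4.87, 5.68,  3.36, 4.47,  4.12, 5.15),
    albumin    = c(38.49, 3.63, 38.41, 3.21, 38.96, 3.38),
    hemoglobin = c(106.06, 15.70, 110.93, 11.50, 110.79, 13.88),
    ferritin   = c(333.16, 315.14, 203.23, 274.42, 262.26, 296.23),
    tsat       = c(27.87, 12.81, 26.57, 10.09, 27.26, 12.34),
    calcium    = c(2.23, 0.26,  2.31, 0.23,  2.32, 0.24),
    phosphorus = c(1.83, 0.57,  1.80, 0.50,  1.83, 0.52),
    ipth       = c(342.26, 269.78, 392.30, 310.56, 360.31, 298.78),
    alp        = c(92.81, 36.09, 93.65, 34.16, 93.09, 57.71),
    ktv        = c(1.18, 0.31,  2.00, 0.25,  1.52, 0.17),
    b2m_pre    = c(37.16, 14.96, 35.81, 8.56, 36.91, 10.78),
    b2m_rr     = c(54.74, 21.86, 83.09, 4.32, 76.38, 5.61),
    bun_pre    = c(26.81, 6.74, 28.53, 6.31, 26.83, 6.76),
    hco3_delta = c(5.14, 2.25,  5.12, 2.35,  4.87, 2.23),
    k_delta    = c(1.28, 0.75,  1.26, 1.05,  1.32, 0.86),
    na_delta   = c(3.31, 2.68,  3.45, 2.64,  3.31, 2.79)
  )
  colnames(x) <- c("m0", "s0", "m1", "s1", "m2", "s2")
  x
})

.FAMILY <- c(
  wbc = "lognormal", crp = "lognormal", albumin = "normal",
  hemoglobin = "normal", ferritin = "lognormal", tsat = "lognormal",
  calcium = "normal", phosphorus = "normal", ipth = "lognormal",
  alp = "lognormal", ktv = "normal", b2m_pre = "lognormal",
  b2m_rr = "truncated_normal", bun_pre = "normal",
  hco3_delta = "truncated_normal", k_delta = "truncated_normal",
  na_delta = "truncated_normal"
)

.BOUNDS <- list(
  tsat = c(0, 100), b2m_rr = c(0, 100),
  hco3_delta = c(0, Inf), k_delta = c(0, Inf), na_delta = c(0, Inf),
  # physical floors for Gaussian-family concentrations; the floor sits more
  # than 3 SD below every phenotype mean, so moments are unaffected in
  # practice and the tail is simply clipped by truncation
  wbc = c(0, Inf), crp = c(0, Inf), albumin = c(0, Inf),
  hemoglobin = c(0, Inf), ferritin = c(0, Inf), calcium = c(0, Inf),
  phosphorus = c(0, Inf), ipth = c(0, Inf), alp = c(0, Inf),
  ktv = c(0, Inf), b2m_pre = c(0, Inf), bun_pre = c(0, Inf)
)

#' Default synthetic-cohort specification
#'
#' Group sizes (236, 294, 677), mixture weights = sizes/1207, per-phenotype
#' per-indicator mean/SD/family from the published phenotype table, MCAR
#' missing rate 0.0034 (51 missing cells over a 1,271 x ~11 imputable-column
#' grid), contamination rate 0.05 with 6-SD displacement outliers.
#'
#' @param seed Integer seed stored in the spec (default 20240101).
#' @return An object of class `hd_synth_spec`: a fully serializable list
#'   with fields `group_sizes`, `weights`, `params` (long data.frame with
#'   `indicator`, `phenotype`, `mean`, `sd`, `family`, `lower`, `upper`),
#'   `missing_rate`, `outlier_rate`, `outlier_magnitude`, `copula_rho`
#'   (`NA` = independent marginals), `seed`.
#' @export
default_spec <- function(seed = 20240101) {
  ind <- rownames(.PHENOTYPE_PARAMS)
  params <- do.call(rbind, lapply(0:2, function(ph) {
    data.frame(
      indicator = ind, phenotype = ph,
      mean = .PHENOTYPE_PARAMS[, 2 * ph + 1],
      sd = .PHENOTYPE_PARAMS[, 2 * ph + 2],
      family = unname(.FAMILY[ind]),
      lower = vapply(ind, function(i) if (i %in% names(.BOUNDS)) .BOUNDS[[i]][1] else -Inf, 0),
      upper = vapply(ind, function(i) if (i %in% names(.BOUNDS)) .BOUNDS[[i]][2] else Inf, 0),
      row.names = NULL
    )
  }))
  synth_spec(group_sizes = c(236L, 294L, 677L), params = params,
             missing_rate = 0.0034, outlier_rate = 0.05,
             outlier_magnitude = 6, copula_rho = NA_real_, seed = seed)
}

#' Build and validate a synthetic-cohort specification
#' @param group_sizes Integer vector of 3 phenotype sizes.
#' @param params Long-format parameter data.frame (see [default_spec()]).
#' @param missing_rate,outlier_rate,outlier_magnitude,copula_rho,seed See
#'   [default_spec()].
#' @return An `hd_synth_spec`.
#' @export
synth_spec <- function(group_sizes, params, missing_rate = 0,
                       outlier_rate = 0, outlier_magnitude = 6,
                       copula_rho = NA_real_, seed = 1L) {
  if (any(params$sd <= 0)) stop("all sds must be > 0")
  if (any(params$family == "lognormal" & params$mean <= 0))
    stop("lognormal indicators need mean > 0")
  w <- group_sizes / sum(group_sizes)
  stopifnot(abs(sum(w) - 1) < 1e-9)
  structure(
    list(group_sizes = as.integer(group_sizes), weights = w, params = params,
         missing_rate = missing_rate, outlier_rate = outlier_rate,
         outlier_magnitude = outlier_magnitude, copula_rho = copula_rho,
         seed = as.integer(seed)),
    class = "hd_synth_spec"
  )
}

# truncated-normal helpers ---------------------------------------------------

# mean/sd of N(mu, sigma) truncated to [a, b]
.trunc_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  pa <- stats::dnorm(al); pb <- stats::dnorm(be)
  pa[!is.finite(al)] <- 0; pb[!is.finite(be)] <- 0
  m <- mu + sigma * (pa - pb) / Z
  t1 <- ifelse(is.finite(al), al * pa, 0)
  t2 <- ifelse(is.finite(be), be * pb, 0)
  v <- sigma^2 * (1 + (t1 - t2) / Z - ((pa - pb) / Z)^2)
  c(mean = m, sd = sqrt(pmax(v, 0)))
}

# underlying (mu, sigma) whose [a,b]-truncation has the target mean/sd
.trunc_solve <- function(target_mean, target_sd, a, b) {
  obj <- function(par) {
    mo <- .trunc_moments(par[1], exp(par[2]), a, b)
    (mo[1] - target_mean)^2 / target_sd^2 + (mo[2] - target_sd)^2 / target_sd^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# quantile function for one marginal, including bound truncation
.marginal_quantile <- function(u, mean, sd, family, lower, upper) {
  if (family == "normal") {
    if (is.finite(lower) || is.finite(upper)) {
      # plain tail clipping: bounds sit far out, so mean/sd are preserved
      pa <- stats::pnorm(lower, mean, sd)
      pb <- stats::pnorm(upper, mean, sd)
      stats::qnorm(pa + u * (pb - pa), mean, sd)
    } else stats::qnorm(u, mean, sd)
  } else if (family == "lognormal") {
    s2 <- log(1 + (sd / mean)^2)
    mu <- log(mean) - s2 / 2
    sig <- sqrt(s2)
    if (is.finite(upper)) {
      # truncate the matched lognormal at the physical bound
      pu <- stats::plnorm(upper, mu, sig)
      stats::qlnorm(u * pu, mu, sig)
    } else stats::qlnorm(u, mu, sig)
  } else if (family == "truncated_normal") {
    par <- .trunc_solve(mean, sd, lower, upper)
    pa <- stats::pnorm(lower, par[1], par[2])
    pb <- stats::pnorm(upper, par[1], par[2])
    stats::qnorm(pa + u * (pb - pa), par[1], par[2])
  } else stop("unknown family: ", family)
}

# n x p uniforms; optionally block-correlated via a Gaussian copula within
# registry domain groups (exchangeable correlation rho)
.draw_uniforms <- function(n, ind, rho, registry) {
  z <- matrix(stats::rnorm(n * length(ind)), n, length(ind),
              dimnames = list(NULL, ind))
  if (!is.na(rho) && rho != 0) {
    groups <- registry$domain_group[match(ind, registry$name)]
    for (g in unique(groups)) {
      idx <- which(groups == g)
      if (length(idx) < 2) next
      S <- matrix(rho, length(idx), length(idx)); diag(S) <- 1
      z[, idx] <- z[, idx] %*% chol(S)
    }
  }
  stats::pnorm(z)
}

#' Generate a labeled synthetic cohort
#'
#' Deterministic given `spec$seed`. Records are generated phenotype block by
#' phenotype block; marginals are independent within phenotype unless
#' `spec$copula_rho` is set, in which case indicators within a registry
#' domain group share an exchangeable Gaussian copula.
#'
#' @param spec An `hd_synth_spec`.
#' @param registry Variable registry (default [default_registry()]).
#' @return An object of class `hd_labeled_cohort`: list with `table`
#'   (an `hd_cohort` of the 17 base indicators), `true_labels` (0/1/2),
#'   `outlier_flags` (all `FALSE` until [inject_outliers()]).
#' @export
generate <- function(spec, registry = default_registry()) {
  set.seed(spec$seed)
  ind <- unique(spec$params$indicator)
  blocks <- lapply(0:2, function(ph) {
    n <- spec$group_sizes[ph + 1]
    pars <- spec$params[spec$params$phenotype == ph, ]
    pars <- pars[match(ind, pars$indicator), ]
    u <- .draw_uniforms(n, ind, spec$copula_rho, registry)
    vals <- vapply(seq_along(ind), function(j) {
      .marginal_quantile(u[, j], pars$mean[j], pars$sd[j], pars$family[j],
                         pars$lower[j], pars$upper[j])
    }, numeric(n))
    if (n == 1) vals <- matrix(vals, 1)
    colnames(vals) <- ind
    vals
  })
  vals <- do.call(rbind, blocks)
  labels <- rep(0:2, times = spec$group_sizes)
  reg <- registry[match(ind, registry$name), ]
  rownames(reg) <- NULL
  structure(
    list(table = cohort_table(vals, reg),
         true_labels = labels,
         outlier_flags = rep(FALSE, nrow(vals)),
         spec = spec),
    class = "hd_labeled_cohort"
  )
}

#' @export
print.hd_labeled_cohort <- function(x, ...) {
  cat("<hd_labeled_cohort> n=", length(x$true_labels), ", phenotype sizes: ",
      paste(table(x$true_labels), collapse = "/"),
      ", outliers flagged: ", sum(x$outlier_flags), "\n", sep = "")
  invisible(x)
}

#' Inject MCAR missingness into a labeled cohort
#'
#' Cells are masked uniformly at random, independent of values and labels.
#' Rates at or above 5% are refused unless `override = TRUE`, mirroring the
#' justification threshold for single median imputation.
#'
#' @param cohort An `hd_labeled_cohort`.
#' @param rate Fraction of cells to mask, in \[0, 0.05).
#' @param seed Integer seed.
#' @param override Allow rates >= 0.05.
#' @return The cohort with updated table mask.
#' @export
inject_missing <- function(cohort, rate, seed, override = FALSE) {
  if (rate < 0) stop("rate must be non-negative")
  if (rate >= 0.05 && !override)
    stop("missing rate ", rate, " >= 0.05; set override = TRUE to force")
  if (rate == 0) return(cohort)
  set.seed(seed)
  v <- cohort$table$values
  hit <- matrix(stats::runif(length(v)) < rate, nrow(v), ncol(v))
  v[hit] <- NA_real_
  cohort$table <- cohort_table(v, cohort$table$registry, ids = cohort$table$ids)
  cohort
}

# mixture-wide SD per indicator (law of total variance over phenotypes)
.mixture_sd <- function(spec) {
  ind <- unique(spec$params$indicator)
  w <- spec$weights
  vapply(ind, function(i) {
    p <- spec$params[spec$params$indicator == i, ]
    p <- p[order(p$phenotype), ]
    m <- sum(w * p$mean)
    sqrt(sum(w * (p$sd^2 + p$mean^2)) - m^2)
  }, 0)
}

#' Append contaminating outlier records
#'
#' Appends records drawn from the global mixture in which a random subset
#' (at least one third) of indicators is displaced by +-`magnitude` mixture
#' SDs, then clamped to physical bounds. The appended count is chosen so
#' the flagged fraction of the final table equals `rate`
#' (`round(rate * n / (1 - rate))`; 1,207 clean records at rate 0.0504 give
#' 64 appended, 1,271 total).
#'
#' @param cohort An `hd_labeled_cohort` (clean).
#' @param rate Target contaminated fraction of the final table, in \[0, 0.2).
#' @param magnitude Displacement in mixture-SD units (default 6).
#' @param seed Integer seed.
#' @return The cohort with appended records, labels (sampled mixture
#'   component) and `outlier_flags` updated.
#' @export
inject_outliers <- function(cohort, rate, magnitude = 6, seed = 1L) {
  if (rate < 0 || rate >= 0.2) stop("rate must lie in [0, 0.2)")
  if (rate == 0) return(cohort)
  spec <- cohort$spec
  n <- length(cohort$true_labels)
  m <- round(rate * n / (1 - rate))
  if (m == 0) return(cohort)
  set.seed(seed)
  ind <- colnames(cohort$table$values)
  mix_sd <- .mixture_sd(spec)[ind]
  phen <- sample(0:2, m, replace = TRUE, prob = spec$weights)
  lower <- vapply(ind, function(i) spec$params$lower[spec$params$indicator == i][1], 0)
  upper <- vapply(ind, function(i) spec$params$upper[spec$params$indicator == i][1], 0)
  rows <- matrix(NA_real_, m, length(ind), dimnames = list(NULL, ind))
  p <- length(ind)
  for (r in seq_len(m)) {
    pars <- spec$params[spec$params$phenotype == phen[r], ]
    pars <- pars[match(ind, pars$indicator), ]
    u <- stats::runif(p)
    x <- vapply(seq_len(p), function(j) {
      .marginal_quantile(u[j], pars$mean[j], pars$sd[j], pars$family[j],
                         pars$lower[j], pars$upper[j])
    }, 0)
    k <- sample(ceiling(p / 3):p, 1)
    idx <- sample(p, k)
    x[idx] <- x[idx] + sample(c(-1, 1), k, replace = TRUE) * magnitude * mix_sd[idx]
    x <- pmin(pmax(x, lower), upper)
    # keep concentrations physical even where no explicit bound is registered
    nonneg <- cohort$table$registry$nonneg[match(ind, cohort$table$registry$name)]
    x[nonneg] <- pmax(x[nonneg], 0)
    # ratio denominators must stay strictly positive (assay floor)
    denom <- ind %in% c("albumin", "hemoglobin")
    x[denom] <- pmax(x[denom], 1)
    rows[r, ] <- x
  }
  vals <- rbind(cohort$table$values, rows)
  cohort$table <- cohort_table(vals, cohort$table$registry)
  cohort$true_labels <- c(cohort$true_labels, phen)
  cohort$outlier_flags <- c(cohort$outlier_flags, rep(TRUE, m))
  cohort
}
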