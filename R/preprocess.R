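#' Robust preprocessing for clustering
#'
#' The preprocessing pipeline standardizes the 22-indicator panel for
#' distance-based clustering: median imputation of missing cells, derivation
#' of the composite indicators, Yeo-Johnson power transformation (lambda by
#' maximum likelihood) of skewed variables, robust scaling by median/IQR,
#' near-zero-variance removal, and a variance-inflation-factor report for
#' collinearity. Fitting and application are strictly separated: a fitted
#' `hd_transform` applied to new data reuses the stored parameters and never
#' re-estimates anything.
#'
#' @name preprocess
NULL

#' Median imputation
#'
#' Replaces every missing cell by its column's observed median and clears
#' the mask. Columns missing at 5% or more are refused unless
#' `override = TRUE` (single imputation is only defensible below that
#' threshold under MCAR).
#'
#' @param table An `hd_cohort`.
#' @param max_missing Per-column guard threshold (default 0.05).
#' @param override Allow columns above the guard.
#' @return A list: `table` (imputed `hd_cohort`), `imputation_values`
#'   (named vector of medians used).
#' @export
impute_median <- function(table, max_missing = 0.05, override = FALSE) {
  frac <- colMeans(table$missing_mask)
  if (any(frac >= max_missing) && !override)
    stop("columns above the ", max_missing, " missing-fraction guard: ",
         paste(names(frac)[frac >= max_missing], collapse = ", "),
         " (set override = TRUE to force)")
  if (any(frac == 1)) stop("all-missing column: ",
                           paste(names(frac)[frac == 1], collapse = ", "))
  v <- table$values
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(v))) {
    miss <- table$missing_mask[, j]
    if (any(miss)) v[miss, j] <- med[j]
  }
  list(table = cohort_table(v, table$registry, ids = table$ids),
       imputation_values = med)
}

# Yeo-Johnson -----------------------------------------------------------------

#' Apply the Yeo-Johnson transformation
#'
#' Piecewise power transform, strictly monotone for every finite `lambda`:
#' for x >= 0, ((x+1)^lambda - 1)/lambda (log(x+1) at lambda = 0); for
#' x < 0, -(((-x+1)^(2-lambda) - 1))/(2-lambda) (-log(-x+1) at lambda = 2).
#'
#' @param x Numeric vector.
#' @param lambda Finite transformation parameter.
#' @return Transformed vector.
#' @export
yeo_johnson_apply <- function(x, lambda) {
  stopifnot(is.finite(lambda))
  out <- x
  pos <- !is.na(x) & x >= 0
  neg <- !is.na(x) & x < 0
  if (abs(lambda) > 1e-10) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-10) {
    out[neg] <- -(((-x[neg] + 1)^(2 - lambda)) - 1) / (2 - lambda)
  } else {
    out[neg] <- -log1p(-x[neg])
  }
  out
}

#' Fit the Yeo-Johnson parameter by maximum likelihood
#'
#' Profiles out the Gaussian variance and maximizes the exact
#' log-likelihood, log|J| - n/2 log(sigma-hat^2(lambda)), over
#' lambda in \[-5, 5\] by bounded one-dimensional optimization
#' (tolerance 1e-6). The Jacobian term is
#' (lambda - 1) * sum(sign(x) * log(|x| + 1)).
#'
#' @param x Numeric vector with at least 10 finite values and nonzero
#'   variance.
#' @return The fitted lambda.
#' @export
yeo_johnson_fit <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 10) stop("need at least 10 finite values")
  if (stats::sd(x) < 1e-12) stop("degenerate input: zero variance")
  n <- length(x)
  jac <- sum(sign(x) * log1p(abs(x)))
  negll <- function(lambda) {
    z <- yeo_johnson_apply(x, lambda)
    s2 <- stats::var(z) * (n - 1) / n
    if (!is.finite(s2) || s2 <= 0) return(Inf)
    n / 2 * log(s2) - (lambda - 1) * jac
  }
  stats::optimize(negll, c(-5, 5), tol = 1e-6)$minimum
}

# scaling and screening --------------------------------------------------------

#' Robust scaling by median and IQR
#'
#' Column-wise (x - median)/IQR with type-7 (linearly interpolated)
#' quantiles. Columns with zero IQR are excluded from scaling and reported.
#'
#' @param m Numeric matrix.
#' @return List: `scaled` (matrix of scaled retained columns), `centers`,
#'   `scales` (named vectors over retained columns), `excluded` (names of
#'   zero-IQR columns).
#' @export
robust_scale_fit_apply <- function(m) {
  centers <- apply(m, 2, stats::median)
  scales <- apply(m, 2, stats::IQR, type = 7)
  keep <- scales > 0
  scaled <- sweep(sweep(m[, keep, drop = FALSE], 2, centers[keep]), 2,
                  scales[keep], "/")
  list(scaled = scaled, centers = centers[keep], scales = scales[keep],
       excluded = colnames(m)[!keep])
}

#' Near-zero-variance filter
#'
#' Drops columns with numerical variance below `var_eps`, or whose
#' most-frequent/second-most-frequent value ratio exceeds
#' `freq_ratio_threshold` while the unique-value fraction is below
#' `unique_fraction_threshold`.
#'
#' @param m Numeric matrix.
#' @param freq_ratio_threshold Default 19 (i.e. 95/5).
#' @param unique_fraction_threshold Default 0.1.
#' @param var_eps Variance floor, default 1e-12.
#' @return List: `keep` (logical per column), `report` (data.frame of the
#'   per-column diagnostics).
#' @export
near_zero_variance_filter <- function(m, freq_ratio_threshold = 19,
                                      unique_fraction_threshold = 0.1,
                                      var_eps = 1e-12) {
  stats_per_col <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    tb <- sort(table(x), decreasing = TRUE)
    ratio <- if (length(tb) == 1) Inf else unname(tb[1] / tb[2])
    c(variance = stats::var(x), freq_ratio = ratio,
      unique_fraction = length(tb) / length(x))
  })
  rep_df <- as.data.frame(do.call(rbind, stats_per_col))
  rep_df$column <- colnames(m)
  keep <- rep_df$variance >= var_eps &
    !(rep_df$freq_ratio > freq_ratio_threshold &
        rep_df$unique_fraction < unique_fraction_threshold)
  rep_df$kept <- keep
  list(keep = keep, report = rep_df)
}

#' Variance inflation factors
#'
#' VIF_j = 1/(1 - R^2_j) from an ordinary least-squares regression of column
#' j on all other columns (with intercept). Report-only: the clustering
#' panel deliberately retains composite/component pairs, so nothing is
#' dropped here by default.
#'
#' @param m Numeric matrix with more rows than columns.
#' @return Named numeric vector of VIFs (`Inf` for (near-)perfectly
#'   collinear columns).
#' @export
vif_screen <- function(m) {
  if (nrow(m) <= ncol(m)) stop("need n > p for VIF estimation")
  p <- ncol(m)
  if (p == 1) return(stats::setNames(1, colnames(m)))
  vif <- vapply(seq_len(p), function(j) {
    y <- m[, j]
    X <- m[, -j, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, X), y)
    sst <- sum((y - mean(y))^2)
    if (sst < 1e-24) return(Inf)
    r2 <- 1 - sum(fit$residuals^2) / sst
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  stats::setNames(vif, colnames(m))
}

# fitted model -----------------------------------------------------------------

#' Fit the preprocessing model on a cohort
#'
#' Order: median imputation, composite derivation, Yeo-Johnson on skewed
#' variables (registry hint, or sample |skewness| above
#' `skewness_threshold`), median/IQR scaling, near-zero-variance filter,
#' VIF report. Returns a fitted `hd_transform` carrying everything needed
#' to reproduce the standardized matrix on new data.
#'
#' @param table An `hd_cohort` with the 17 base indicators (composites are
#'   derived internally; pre-derived composite columns are recomputed).
#' @param skewness_threshold Moment-skewness trigger, default 0.75.
#' @param registry Full registry.
#' @param impute_override Passed to [impute_median()].
#' @return An `hd_transform`: list with `imputation_values`, `lambdas`
#'   (named, only transformed columns), `centers`, `scales`,
#'   `retained_columns`, `vif`, `nzv_report`, `standardized` (the training
#'   matrix), plus the configuration used.
#' @export
fit_preprocessor <- function(table, skewness_threshold = 0.75,
                             registry = default_registry(),
                             impute_override = FALSE) {
  imp <- impute_median(table, override = impute_override)
  full <- derive_all(imp$table, registry)
  v <- full$values
  skew_hint <- registry$skewed[match(colnames(v), registry$name)]
  lambdas <- numeric(0)
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    do_yj <- skew_hint[j] || abs(.skewness(x)) > skewness_threshold
    if (do_yj) {
      lam <- yeo_johnson_fit(x)
      v[, j] <- yeo_johnson_apply(x, lam)
      lambdas[colnames(v)[j]] <- lam
    }
  }
  sc <- robust_scale_fit_apply(v)
  nzv <- near_zero_variance_filter(sc$scaled)
  std <- sc$scaled[, nzv$keep, drop = FALSE]
  vif <- vif_screen(std)
  structure(
    list(imputation_values = imp$imputation_values,
         lambdas = lambdas,
         centers = sc$centers, scales = sc$scales,
         retained_columns = colnames(std),
         vif = vif, nzv_report = nzv$report,
         standardized = std,
         skewness_threshold = skewness_threshold,
         registry = registry),
    class = "hd_transform"
  )
}

#' @export
print.hd_transform <- function(x, ...) {
  cat("<hd_transform> ", length(x$retained_columns), " retained columns, ",
      length(x$lambdas), " Yeo-Johnson transformed\n", sep = "")
  invisible(x)
}

#' Apply a fitted preprocessing model to new data
#'
#' Reuses the stored imputation medians, lambdas, centers and scales; no
#' statistic of the new table influences the result.
#'
#' @param model An `hd_transform`.
#' @param table An `hd_cohort` with the base indicators.
#' @return Standardized numeric matrix over `model$retained_columns`.
#' @export
apply_preprocessor <- function(model, table) {
  v <- table$values
  need <- names(model$imputation_values)
  if (!all(need %in% colnames(v)))
    stop("schema mismatch: missing columns ",
         paste(setdiff(need, colnames(v)), collapse = ", "))
  v <- v[, need, drop = FALSE]
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (any(miss)) v[miss, j] <- model$imputation_values[need[j]]
  }
  full <- derive_all(cohort_table(v, table$registry[match(need, table$registry$name), ],
                                  ids = table$ids),
                     model$registry)
  v <- full$values
  for (nm in names(model$lambdas))
    v[, nm] <- yeo_johnson_apply(v[, nm], model$lambdas[[nm]])
  cols <- model$retained_columns
  sweep(sweep(v[, cols, drop = FALSE], 2, model$centers[cols]), 2,
        model$scales[cols], "/")
}

# moment coefficient of skewness (g1)
.skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(0)
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s < 1e-12) return(0)
  mean((x - m)^3) / s^3
}

#' Serialize a fitted preprocessing model to JSON
#' @param model An `hd_transform`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(model, path) {
  obj <- list(
    format = "hd_transform/1",
    imputation_values = as.list(model$imputation_values),
    lambdas = as.list(model$lambdas),
    centers = as.list(model$centers),
    scales = as.list(model$scales),
    retained_columns = model$retained_columns,
    skewness_threshold = model$skewness_threshold
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
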