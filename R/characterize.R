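#' Phenotype characterization
#'
#' Per-indicator group comparisons across phenotypes: classical one-way
#' ANOVA decomposition with Bonferroni-corrected pairwise Welch tests for
#' approximately normal variables, Kruskal-Wallis for skewed ones,
#' eta-squared effect sizes (computable from raw data or from printed group
#' summary statistics), Z-score profiling of phenotype signatures, and
#' deterministic phenotype naming by clearance ordering. Also includes the
#' treatment-confounding tools: prescription-explained variance (R^2) and
#' residual phenotype tests.
#'
#' @name characterize
NULL

#' One-way ANOVA decomposition
#'
#' @param values Numeric vector.
#' @param labels Group labels (at least 2 groups).
#' @return List with `F`, `p`, `SSb`, `SSw`, `df1`, `df2`. All-equal values
#'   give F = 0, p = 1.
#' @export
anova_oneway <- function(values, labels) {
  f <- factor(labels)
  k <- nlevels(f)
  if (k < 2) stop("need at least 2 groups")
  n <- length(values)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in levels(f)) {
    x <- values[f == g]
    ssb <- ssb + length(x) * (mean(x) - grand)^2
    ssw <- ssw + sum((x - mean(x))^2)
  }
  df1 <- k - 1; df2 <- n - k
  if (ssw < 1e-24) {
    Fstat <- if (ssb < 1e-24) 0 else Inf
  } else {
    Fstat <- (ssb / df1) / (ssw / df2)
  }
  p <- if (is.infinite(Fstat)) 0 else stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  list(F = Fstat, p = p, SSb = ssb, SSw = ssw, df1 = df1, df2 = df2)
}

#' Eta-squared from raw data
#' @inheritParams anova_oneway
#' @return SSb/(SSb + SSw); 0 when the total sum of squares vanishes.
#' @export
eta_squared_raw <- function(values, labels) {
  a <- anova_oneway(values, labels)
  tot <- a$SSb + a$SSw
  if (tot < 1e-24) return(0)
  a$SSb / tot
}

#' Eta-squared from group summary statistics
#'
#' Reconstructs the ANOVA decomposition from per-group means, SDs and sizes:
#' SSb = sum n_i (m_i - m)^2 around the size-weighted grand mean, and
#' SSw = sum (n_i - 1) s_i^2. This makes printed summary tables directly
#' auditable: applying it to published phenotype means/SDs reproduces the
#' published effect sizes.
#'
#' @param means,sds,ns Per-group mean, SD and size vectors (ns >= 2 each).
#' @return SSb/(SSb + SSw); 0 when the total vanishes.
#' @export
#' @examples
#' # Kt/V across three phenotypes of sizes 236/294/677
#' eta_squared_summary(c(1.18, 2.00, 1.52), c(0.31, 0.25, 0.17),
#'                     c(236, 294, 677))
eta_squared_summary <- function(means, sds, ns) {
  stopifnot(length(means) == length(sds), length(sds) == length(ns),
            all(ns >= 2), all(sds >= 0))
  grand <- sum(ns * means) / sum(ns)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  if (ssb + ssw < 1e-24) return(0)
  ssb / (ssb + ssw)
}

#' Bonferroni-corrected pairwise Welch tests
#'
#' All pairwise two-sample Welch t-tests between groups; a pair is
#' significant when p < alpha/m with m the number of pairs. Pairs are
#' reported as `"i-j"` strings over 0-based sorted group codes (so three
#' phenotypes yield subsets of `{"0-1", "0-2", "1-2"}`).
#'
#' @inheritParams anova_oneway
#' @param alpha Family-wise level (default 0.05).
#' @return Character vector of significant pairs (possibly empty), with all
#'   pairwise p-values in the `"p_values"` attribute.
#' @export
bonferroni_pairwise <- function(values, labels, alpha = 0.05) {
  f <- factor(labels)
  lev <- levels(f)
  k <- length(lev)
  if (k < 2) stop("need at least 2 groups")
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  pv <- apply(pairs, 2, function(pr) {
    a <- values[f == lev[pr[1]]]
    b <- values[f == lev[pr[2]]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    stats::t.test(a, b)$p.value
  })
  nm <- apply(pairs, 2, function(pr)
    paste0(pr[1] - 1, "-", pr[2] - 1))
  sig <- nm[pv < alpha / m]
  structure(sig, p_values = stats::setNames(pv, nm))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with a chi-squared reference distribution (delegates to
#' [stats::kruskal.test()]); warns when the total sample is too small for
#' the chi-squared approximation.
#'
#' @inheritParams anova_oneway
#' @return List with `H` and `p` (all-tied values give H = 0, p = 1).
#' @export
kruskal_wallis <- function(values, labels) {
  f <- factor(labels)
  if (nlevels(f) < 2) stop("need at least 2 groups")
  if (length(values) < 5)
    warning("fewer than 5 observations: chi-squared approximation is poor")
  if (length(unique(values)) == 1) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(values, f)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Z-score profile of phenotypes
#'
#' Per indicator and phenotype: (group mean - overall mean)/overall SD, the
#' overall SD being the population SD (denominator n) of the analysis
#' table. Size-weighted Z-scores therefore sum to zero per indicator.
#'
#' @param values Numeric matrix (records x indicators).
#' @param labels Phenotype labels, complete.
#' @return Matrix phenotype x indicator of standardized deviations; zero
#'   where the overall SD vanishes.
#' @export
zscore_profile <- function(values, labels) {
  values <- as.matrix(values)
  f <- factor(labels)
  mu <- colMeans(values)
  sdp <- sqrt(colMeans(sweep(values, 2, mu)^2))
  z <- matrix(0, nlevels(f), ncol(values),
              dimnames = list(levels(f), colnames(values)))
  for (g in levels(f)) {
    gm <- colMeans(values[f == g, , drop = FALSE])
    z[g, ] <- ifelse(sdp > 0, (gm - mu) / sdp, 0)
  }
  z
}

#' Full phenotype profile of a cohort
#'
#' Builds the published-table-shaped characterization: per indicator the
#' per-phenotype mean/SD/size, both the ANOVA F and Kruskal-Wallis H with
#' their p-values, the test routed to by the registry skewness hint,
#' eta-squared with its effect band (<0.06 small, 0.06-0.14 medium, >0.14
#' large), and the Bonferroni-significant pair set; plus the Z-score
#' matrix.
#'
#' @param table An `hd_cohort` (22-indicator panel).
#' @param labels Phenotype labels (0-based).
#' @param alpha Pairwise family-wise level (default 0.05).
#' @return An `hd_profile`: list with `table` (data.frame, one row per
#'   indicator), `zscores`, `group_sizes`.
#' @export
characterize_phenotypes <- function(table, labels, alpha = 0.05) {
  v <- table$values
  f <- factor(labels)
  lev <- levels(f)
  skew_hint <- table$registry$skewed[match(colnames(v), table$registry$name)]
  rows <- lapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    a <- anova_oneway(x, f)
    kw <- kruskal_wallis(x, f)
    eta <- eta_squared_raw(x, f)
    sig <- bonferroni_pairwise(x, f, alpha)
    gm <- tapply(x, f, mean)
    gs <- tapply(x, f, stats::sd)
    band <- if (eta < 0.06) "small" else if (eta <= 0.14) "medium" else "large"
    out <- data.frame(indicator = colnames(v)[j],
                      test = if (skew_hint[j]) "kruskal_wallis" else "anova",
                      F = a$F, p_anova = a$p, H = kw$H, p_kruskal = kw$p,
                      eta_squared = eta, effect_band = band,
                      pairwise = paste(sig, collapse = ", "))
    for (g in seq_along(lev)) {
      out[[paste0("mean_", g - 1)]] <- unname(gm[lev[g]])
      out[[paste0("sd_", g - 1)]] <- unname(gs[lev[g]])
    }
    out
  })
  structure(list(table = do.call(rbind, rows),
                 zscores = zscore_profile(v, labels),
                 group_sizes = as.integer(table(f))),
            class = "hd_profile")
}

#' @export
print.hd_profile <- function(x, ...) {
  cat("<hd_profile> ", nrow(x$table), " indicators x ",
      length(x$group_sizes), " phenotypes (sizes ",
      paste(x$group_sizes, collapse = "/"), ")\n", sep = "")
  invisible(x)
}

#' Export a phenotype profile as a summary-table CSV
#' @param profile An `hd_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(profile$table, path, row.names = FALSE)
  invisible(path)
}

#' Name the three phenotypes by clearance ordering
#'
#' Orders clusters by their mean MSMCI on the original scale (Kt/V as
#' fallback when MSMCI is absent): lowest clearance becomes
#' `"high retention-inflammatory"`, highest `"optimal clearance"`, middle
#' `"intermediate-stable"`. Any k other than 3 yields generic
#' `"cluster-i"` names. The mapping is attached to the model.
#'
#' @param model An `hd_kmeans`.
#' @param table The analysis `hd_cohort` on the original scale.
#' @param labels Cluster labels of `table` rows (default the model's
#'   training labels).
#' @return The model with `name_map` filled (named character vector indexed
#'   by 0-based cluster).
#' @export
name_phenotypes <- function(model, table, labels = model$labels) {
  k <- model$k
  cl <- as.character(0:(k - 1))
  if (k != 3) {
    model$name_map <- stats::setNames(paste0("cluster-", 0:(k - 1)), cl)
    return(model)
  }
  key <- if ("msmci" %in% colnames(table$values)) "msmci" else "ktv"
  cent <- tapply(table$values[, key], factor(labels, levels = 0:2), mean)
  if (anyDuplicated(cent))
    stop("exact clearance tie between centroids; name phenotypes manually")
  ord <- order(cent)  # low -> high clearance
  nm <- character(3)
  nm[ord[1]] <- "high retention-inflammatory"
  nm[ord[2]] <- "intermediate-stable"
  nm[ord[3]] <- "optimal clearance"
  model$name_map <- stats::setNames(nm, cl)
  model
}

#' Prescription-explained variance
#'
#' Ordinary least squares of a biomarker on treatment-prescription columns,
#' with intercept; returns R^2 = 1 - SSE/SST.
#'
#' @param response Numeric vector.
#' @param predictors Numeric matrix, n > p + 1.
#' @return R^2, with the fitted residuals in the `"residuals"` attribute.
#' @export
variance_explained <- function(response, predictors) {
  predictors <- as.matrix(predictors)
  if (nrow(predictors) <= ncol(predictors) + 1) stop("need n > p + 1")
  if (any(apply(predictors, 2, stats::sd) == 0))
    stop("singular design: constant predictor column")
  fit <- stats::lm.fit(cbind(1, predictors), response)
  sst <- sum((response - mean(response))^2)
  r2 <- 1 - sum(fit$residuals^2) / sst
  structure(r2, residuals = fit$residuals)
}

#' Phenotype test on treatment-adjusted residuals
#'
#' Regresses the biomarker on the prescription matrix, then runs the
#' one-way ANOVA of the residuals across phenotype labels: a significant F
#' after adjustment indicates phenotype differences not attributable to
#' prescriptions.
#'
#' @inheritParams variance_explained
#' @param labels Phenotype labels.
#' @return List with `F`, `p` (plus the underlying decomposition).
#' @export
residual_group_test <- function(response, predictors, labels) {
  r2 <- variance_explained(response, predictors)
  res <- attr(r2, "residuals")
  anova_oneway(res, labels)
}
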