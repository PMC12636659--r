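# helper: rescale a sample to exact mean m and SD s
exact_moments <- function(x, m, s) m + (x - mean(x)) / sd(x) * s

test_that("one-way ANOVA decomposition matches closed form and stats::", {
  set.seed(1)
  a <- exact_moments(rnorm(10), 0, 1)
  b <- exact_moments(rnorm(10), 1, 1)
  res <- anova_oneway(c(a, b), rep(0:1, each = 10))
  expect_equal(res$F, 5.0)          # SSb = 5, SSw/df = 1
  expect_equal(res$SSb, 5.0)
  expect_equal(res$SSw, 18.0)       # 9 * 1 + 9 * 1

  same <- c(1, 2, 3, 1, 2, 3)
  res2 <- anova_oneway(same, rep(0:1, each = 3))
  expect_equal(res2$F, 0)
  expect_equal(res2$p, 1)
  expect_error(anova_oneway(1:5, rep(1, 5)), "2 groups")

  # agreement with the standard library on random data
  set.seed(2)
  x <- rnorm(60); g <- sample(0:2, 60, replace = TRUE)
  ref <- oneway.test(x ~ factor(g), var.equal = TRUE)
  got <- anova_oneway(x, g)
  expect_equal(got$F, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
})

test_that("eta-squared from raw data equals the summary-statistic route", {
  for (case in 1:10) {
    set.seed(case)
    g <- sample(0:2, 40, replace = TRUE, prob = c(0.3, 0.3, 0.4))
    if (length(unique(g)) < 2 || min(table(g)) < 2) next
    x <- rnorm(40, mean = g)
    means <- tapply(x, g, mean)
    sds <- tapply(x, g, sd)
    ns <- as.numeric(table(g))
    expect_equal(eta_squared_raw(x, g),
                 eta_squared_summary(means, sds, ns), tolerance = 1e-12)
  }
  # degenerate limits
  x <- rep(c(0, 5), each = 5)
  expect_equal(eta_squared_raw(x, rep(0:1, each = 5)), 1)
  expect_equal(eta_squared_summary(c(2, 2), c(1, 3), c(5, 5)), 0)
})

test_that("Bonferroni pairwise tests recover separated group structure", {
  set.seed(3)
  x <- c(rnorm(50, 0), rnorm(50, 3), rnorm(50, 6))
  g <- rep(0:2, each = 50)
  sig <- bonferroni_pairwise(x, g)
  expect_setequal(as.character(sig), c("0-1", "0-2", "1-2"))
  expect_length(bonferroni_pairwise(rep(1, 30), rep(0:2, 10)), 0)
  # two groups: plain t-test threshold (m = 1)
  y <- c(rnorm(30, 0), rnorm(30, 2))
  p <- attr(bonferroni_pairwise(y, rep(0:1, each = 30)), "p_values")
  expect_length(p, 1)
  expect_equal(names(p), "0-1")
})

test_that("Kruskal-Wallis matches hand ranks and is rank-invariant", {
  expect_warning(res <- kruskal_wallis(c(1, 2, 3, 4), c(0, 0, 1, 1)),
                 "approximation")
  expect_equal(res$H, 2.4)
  expect_equal(kruskal_wallis(rep(2, 10), rep(0:1, 5))$H, 0)
  set.seed(4)
  x <- rlnorm(40); g <- sample(0:1, 40, replace = TRUE)
  expect_equal(kruskal_wallis(x, g)$H, kruskal_wallis(log(x), g)$H)
})

test_that("Z-score profiles are population-standardized and mass-balanced", {
  v <- matrix(c(rep(-1, 10), rep(1, 10)), ncol = 1)
  z <- zscore_profile(v, rep(0:1, each = 10))
  expect_equal(as.numeric(z), c(-1, 1))  # overall population SD is 1
  expect_equal(unname(zscore_profile(v, rep(0, 20))[1, 1]), 0)
  # weighted sum of z-scores over phenotypes vanishes per indicator
  set.seed(5)
  m <- matrix(rnorm(300), 100, 3)
  g <- sample(0:2, 100, replace = TRUE)
  z2 <- zscore_profile(m, g)
  w <- as.numeric(table(g)) / 100
  expect_true(all(abs(colSums(z2 * w)) < 1e-10))
})

test_that("phenotype naming follows the clearance ordering", {
  lab <- generate(separated_spec(seed = 71))
  panel <- derive_all(lab$table)
  std <- fit_preprocessor(lab$table)$standardized
  model <- kmeans_fit(std, 3, seed = 72, n_init = 5)
  named <- name_phenotypes(model, panel)
  msm <- tapply(panel$values[, "msmci"], model$labels, mean)
  expect_equal(unname(named$name_map[as.character(which.min(msm) - 1)]),
               "high retention-inflammatory")
  expect_equal(unname(named$name_map[as.character(which.max(msm) - 1)]),
               "optimal clearance")
  # names attach to centroids, not to index order
  perm_labels <- (model$labels + 1L) %% 3L
  model2 <- model
  model2$labels <- perm_labels
  named2 <- name_phenotypes(model2, panel, labels = perm_labels)
  for (cl in 0:2)
    expect_equal(unname(named2$name_map[as.character((cl + 1) %% 3)]),
                 unname(named$name_map[as.character(cl)]))
  # non-three k falls back to generic names
  m4 <- kmeans_fit(std, 4, seed = 73, n_init = 3)
  expect_equal(unname(name_phenotypes(m4, panel, m4$labels)$name_map),
               paste0("cluster-", 0:3))
})

test_that("full profile carries tests, effect bands and group moments", {
  lab <- generate(separated_spec(seed = 75))
  panel <- derive_all(lab$table)
  prof <- characterize_phenotypes(panel, lab$true_labels)
  expect_equal(nrow(prof$table), 22)
  expect_equal(sum(prof$group_sizes), length(lab$true_labels))
  expect_true(all(prof$table$eta_squared >= 0 & prof$table$eta_squared <= 1))
  ktv_row <- prof$table[prof$table$indicator == "ktv", ]
  expect_equal(ktv_row$effect_band, "large")
  expect_equal(ktv_row$pairwise, "0-1, 0-2, 1-2")
  spec <- separated_spec(seed = 75)
  target <- spec$params$mean[spec$params$indicator == "ktv" &
                               spec$params$phenotype == 1]
  expect_equal(ktv_row$mean_1, target, tolerance = 0.02)
  expect_equal(dim(prof$zscores), c(3L, 22L))
})

test_that("prescription-variance tools behave under known designs", {
  set.seed(6)
  X <- matrix(rnorm(300), 100, 3)
  y <- X %*% c(1, -2, 0.5)
  expect_equal(as.numeric(variance_explained(y, X)), 1)
  expect_error(variance_explained(y, cbind(X, 1)), "singular")
  # independent response: R^2 stays small at this n/p
  y2 <- rnorm(100)
  expect_lt(as.numeric(variance_explained(y2, X)), 0.15)
  # phenotype effect orthogonal to prescriptions survives adjustment
  g <- rep(0:1, each = 50)
  y3 <- g * 2 + rnorm(100, 0, 0.5)
  raw <- anova_oneway(y3, g)
  adj <- residual_group_test(y3, X, g)
  expect_equal(adj$F / raw$F, 1, tolerance = 0.25)
  expect_lt(adj$p, 1e-6)
})
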