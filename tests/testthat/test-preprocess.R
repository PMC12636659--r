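test_that("median imputation fills masked cells and honors the 5% guard", {
  reg <- default_registry()[1:2, ]
  v <- cbind(c(1, 2, NA, 4), c(5, 6, 7, 8))
  tab <- cohort_table(v, reg)
  out <- impute_median(tab, override = TRUE)  # tiny fixture exceeds the guard
  expect_equal(unname(out$table$values[3, 1]), 2)  # median of {1,2,4}
  expect_false(any(out$table$missing_mask))
  expect_equal(unname(out$imputation_values[1]), 2)

  complete <- cohort_table(cbind(1:4, 5:8), reg)
  expect_equal(impute_median(complete)$table$values, complete$values)

  # 6% missing refused without override
  v2 <- cbind(c(rnorm(94), rep(NA, 6)), rnorm(100))
  tab2 <- cohort_table(v2, reg)
  expect_error(impute_median(tab2), "guard")
  expect_false(any(impute_median(tab2, override = TRUE)$table$missing_mask))

  allmiss <- cohort_table(cbind(rep(NA_real_, 4), 1:4), reg)
  expect_error(impute_median(allmiss, override = TRUE), "all-missing")
})

test_that("Yeo-Johnson closed forms, monotonicity and library agreement", {
  x <- c(-3, -1, -0.5, 0, 0.2, 1, 2.5, 7)
  expect_equal(yeo_johnson_apply(x, 1), x)                  # identity branch
  expect_equal(yeo_johnson_apply(exp(1) - 1, 0), 1)         # log branch
  expect_equal(yeo_johnson_apply(-(exp(1) - 1), 2), -1)     # negative log branch
  for (lam in c(-2, -0.5, 0, 0.5, 1, 2, 3.5)) {
    y <- yeo_johnson_apply(sort(x), lam)
    expect_true(all(diff(y) > 0), info = paste("lambda", lam))
  }
  skip_if_not_installed("car")
  set.seed(8)
  z <- rnorm(50, 2, 3)
  for (lam in c(-1, 0.3, 1.7))
    expect_equal(yeo_johnson_apply(z, lam),
                 unname(car::yjPower(z, lam)), tolerance = 1e-10)
})

test_that("fitted lambda is near 1 for normal data and recovers the truth", {
  set.seed(42)
  expect_lt(abs(yeo_johnson_fit(rnorm(1000)) - 1), 0.2)
  # data built as inverse-YJ of a normal must recover the generating lambda
  for (lam in c(0, 0.5, 1.5)) {
    set.seed(100 + round(10 * lam))
    z <- rnorm(1000, 0.5, 0.6)
    x <- yj_inverse(z, lam)
    expect_lt(abs(yeo_johnson_fit(x) - lam), 0.15)
  }
  expect_error(yeo_johnson_fit(rep(3, 50)), "variance")
  expect_error(yeo_johnson_fit(1:5), "10 finite")
})

test_that("robust scaling centers at the median and unit-IQR", {
  out <- robust_scale_fit_apply(cbind(a = c(1, 2, 3, 4, 5)))
  expect_equal(as.numeric(out$scaled), c(-1, -0.5, 0, 0.5, 1))
  set.seed(1)
  m <- cbind(x = rlnorm(40), y = rnorm(40), const = rep(2, 40))
  out2 <- robust_scale_fit_apply(m)
  expect_equal(out2$excluded, "const")
  expect_equal(apply(out2$scaled, 2, median), c(x = 0, y = 0))
  expect_equal(apply(out2$scaled, 2, IQR), c(x = 1, y = 1))
})

test_that("near-zero-variance filter applies the frequency-ratio rule", {
  set.seed(2)
  m <- cbind(const = rep(1, 100), normal = rnorm(100),
             rare = c(rep(0, 96), rep(1, 4)))
  out <- near_zero_variance_filter(m)
  expect_equal(unname(out$keep), c(FALSE, TRUE, FALSE))
  expect_equal(out$report$freq_ratio[3], 24)  # 96/4 > 19, unique frac 0.02
})

test_that("VIF matches the closed form and flags collinearity", {
  set.seed(3)
  n <- 400
  a <- rnorm(n); b <- rnorm(n)
  vif <- vif_screen(cbind(a, b))
  expect_true(all(vif < 1.05))
  # empirical correlation r gives VIF 1/(1 - r^2) exactly in the pair case
  c2 <- 0.9 * a + sqrt(1 - 0.81) * rnorm(n)
  r <- cor(a, c2)
  vif2 <- vif_screen(cbind(a, c2))
  expect_equal(unname(vif2["a"]), 1 / (1 - r^2), tolerance = 1e-8)
  vif3 <- vif_screen(cbind(a, b, a2 = a))
  expect_true(is.infinite(vif3[["a"]]) && is.infinite(vif3[["a2"]]))
})

test_that("fit/apply separation: stored parameters fully reproduce output", {
  a <- generate(default_spec(seed = 17))
  a <- inject_missing(a, 0.003, 5)
  model <- fit_preprocessor(a$table)
  expect_equal(length(model$retained_columns), 22)
  # training columns standardized to median 0, IQR 1 exactly
  expect_true(all(abs(apply(model$standardized, 2, median)) < 1e-12))
  expect_true(all(abs(apply(model$standardized, 2, IQR) - 1) < 1e-12))
  # re-applying to the training table reproduces the stored matrix bit-for-bit
  expect_identical(apply_preprocessor(model, a$table),
                   model$standardized)
  # a single record maps to a 22-vector, independent of other apply rows
  one <- cohort_subset(a$table, 4)
  z1 <- apply_preprocessor(model, one)
  expect_equal(dim(z1), c(1L, 22L))
  expect_equal(z1[1, ], apply_preprocessor(model, a$table)[4, ])
  # schema mismatch refused
  cut <- cohort_table(a$table$values[, -3], a$table$registry[-3, ])
  expect_error(apply_preprocessor(model, cut), "schema mismatch")
})

test_that("preprocessing model serializes to JSON", {
  a <- generate(default_spec(seed = 23))
  model <- fit_preprocessor(a$table)
  path <- withr::local_tempfile(fileext = ".json")
  write_transform(model, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$format, "hd_transform/1")
  expect_equal(unlist(obj$retained_columns), model$retained_columns)
  expect_equal(obj$lambdas$crp, unname(model$lambdas["crp"]))
})
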