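test_that("tier-1 extraction returns the six standardized columns in order", {
  lab <- generate(separated_spec(seed = 81))
  model <- fit_preprocessor(lab$table)
  f <- extract_tier1_features(lab$table, model)
  expect_equal(colnames(f), c("ktv", "b2m_rr", "hemoglobin", "ferritin",
                              "ferritin_hb_ratio", "msmci"))
  expect_equal(nrow(f), nrow(lab$table$values))
  expect_identical(f, extract_tier1_features(lab$table, model))  # idempotent
  std <- apply_preprocessor(model, lab$table)
  expect_equal(f[, "msmci"], std[, "msmci"])
})

test_that("stratified split reproduces the published 70:30 arithmetic", {
  labels <- rep(0:2, c(236, 294, 677))
  sp <- stratified_split(labels, 0.7, seed = 1)
  expect_length(sp$train, 844)
  expect_length(sp$test, 363)
  # strata allocated by proportional floor + largest remainder: 165/206/473
  expect_equal(as.numeric(table(labels[sp$train])), c(165, 206, 473))
  # reproducible partition
  sp2 <- stratified_split(labels, 0.7, seed = 1)
  expect_identical(sp$train, sp2$train)
  expect_false(identical(sp$train, stratified_split(labels, 0.7, seed = 2)$train))

  expect_length(stratified_split(rep(0:1, 10), 1.0, seed = 1)$test, 0)
  expect_length(stratified_split(rep(0:1, each = 10), 0.7, seed = 1)$train, 14)
  expect_error(stratified_split(c(0, 1, 1), 0.7), "fewer than 2")
})

test_that("every backend separates a linearly separable toy problem", {
  set.seed(2)
  f <- rbind(matrix(rnorm(100, 0, 0.3), 50, 2),
             matrix(rnorm(100, 4, 0.3), 50, 2))
  colnames(f) <- c("u", "v")
  y <- rep(0:1, each = 50)
  for (alg in c("forest", "boosted", "margin")) {
    clf <- train_classifier(f, y, algorithm = alg, seed = 3)
    expect_equal(mean(clf$predict_class(f) == factor(y)), 1,
                 info = alg)
    sc <- clf$class_scores(f)
    expect_equal(unname(rowSums(sc)), rep(1, 100), tolerance = 1e-6)
    # determinism
    clf2 <- train_classifier(f, y, algorithm = alg, seed = 3)
    expect_identical(clf$predict_class(f), clf2$predict_class(f))
  }
  expect_error(train_classifier(f, rep(1, 100)), "2 classes")
})

test_that("label-shuffled training collapses to the majority rate", {
  set.seed(4)
  f <- matrix(rnorm(600), 300, 2)
  y <- rep(c(0, 1), c(200, 100))   # majority rate 2/3
  sh <- sample(y)
  clf <- train_classifier(f[1:200, ], sh[1:200], "forest", seed = 5)
  acc <- mean(clf$predict_class(f[201:300, ]) == factor(sh[201:300], levels = 0:1))
  expect_lt(abs(acc - 2 / 3), 0.2)
})

test_that("evaluation metrics match their definitional cases", {
  set.seed(6)
  f <- rbind(matrix(rnorm(60, 0, 0.2), 30, 2),
             matrix(rnorm(60, 5, 0.2), 30, 2))
  y <- rep(0:1, each = 30)
  clf <- train_classifier(f, y, "forest", seed = 7)
  rep <- evaluate_classifier(clf, f, y)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$macro_auc, 1)
  expect_equal(rep$rand_concordance, 1)
  expect_equal(unname(rep$per_class[, "precision"]), c(1, 1))
  expect_equal(unname(rep$per_class[, "recall"]), c(1, 1))
  expect_equal(unname(rep$per_class[, "f1"]), c(1, 1))
  expect_equal(as.numeric(diag(rep$confusion)), c(30, 30))
  expect_equal(sum(rep$confusion), 60)
})

test_that("cross-validated Rand concordance is high when learnable", {
  set.seed(8)
  f <- rbind(matrix(rnorm(120, 0, 0.3), 60, 2),
             matrix(rnorm(120, 4, 0.3), 60, 2))
  y <- rep(0:1, each = 60)
  rands <- crossval_classifier(f, y, folds = 4, seed = 9)
  expect_length(rands, 4)
  expect_true(all(rands > 0.9))
})

test_that("the linear scoring surrogate is hand-calculable and faithful", {
  set.seed(10)
  n <- 200
  f <- cbind(sep = c(rnorm(n / 2, -2, 0.5), rnorm(n / 2, 2, 0.5)),
             noise = rnorm(n))
  y <- rep(0:1, each = n / 2)
  hp <- derive_hpcs(f, y)
  # the separating feature dominates the weight table
  expect_gt(abs(hp$weights["1", "sep"]), abs(hp$weights["1", "noise"]) * 3)
  # hand arithmetic on one record reproduces hpcs_score
  rec <- f[17, ]
  scores <- hp$weights[, 1] + hp$weights[, -1] %*% rec
  expect_equal(as.character(hpcs_score(rec, hp)),
               rownames(hp$weights)[which.max(scores)])
  # surrogate agrees with itself across the board and mostly with truth
  pred <- hpcs_score(f, hp)
  expect_gt(mean(pred == factor(y)), 0.95)
  # weights are stored at 2 decimals
  expect_equal(hp$weights, round(hp$weights, 2))
})
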