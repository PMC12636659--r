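#' Simplified six-parameter phenotype classifier
#'
#' The deployment tier of the two-tier framework: a supervised model trained
#' on the tier-2 cluster labels using six universally available biomarkers
#' -- Kt/V, beta2-microglobulin reduction rate, hemoglobin, ferritin, the
#' ferritin-hemoglobin ratio and the Middle-Small Molecule Clearance Index
#' -- so that phenotypes can be assigned from routine monitoring data alone.
#' Backends: a random forest (default), gradient-boosted trees, or an SVM,
#' all behind one predict/score contract. A transparent linear scoring
#' surrogate (HPCS-style, re-derived rather than copied from any published
#' weight table) provides hand-calculable classification.
#'
#' @name tier1
NULL

.TIER1_COLUMNS <- c("ktv", "b2m_rr", "hemoglobin", "ferritin",
                    "ferritin_hb_ratio", "msmci")

#' Extract the standardized six-parameter feature matrix
#'
#' Standardizes the cohort with the fitted tier-2 preprocessing model (the
#' same imputation, transformation and scaling parameters as the clustering
#' space) and returns the six tier-1 columns in their canonical order.
#'
#' @param table An `hd_cohort` with the base indicators.
#' @param transform An `hd_transform` fitted on the tier-2 cohort.
#' @return n x 6 standardized matrix.
#' @export
extract_tier1_features <- function(table, transform) {
  std <- apply_preprocessor(transform, table)
  missing <- setdiff(.TIER1_COLUMNS, colnames(std))
  if (length(missing))
    stop("tier-1 columns not in the standardized panel: ",
         paste(missing, collapse = ", "))
  std[, .TIER1_COLUMNS, drop = FALSE]
}

#' Stratified train/test split
#'
#' Global train size `floor(train_fraction * n)`, allocated across strata by
#' proportional floor plus largest remainder; selection within a stratum is
#' uniform given the seed. 1,207 records in strata (236, 294, 677) at 0.7
#' give 844 train / 363 test.
#'
#' @param labels Stratum labels; every stratum needs >= 2 members.
#' @param train_fraction Default 0.7.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  f <- factor(labels)
  sizes <- table(f)
  if (train_fraction < 1 && any(sizes < 2))
    stop("stratum with fewer than 2 members: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  n <- length(labels)
  target <- floor(train_fraction * n)
  exact <- target * as.numeric(sizes) / n
  alloc <- floor(exact)
  rem <- target - sum(alloc)
  if (rem > 0) {
    extra <- order(exact - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  }
  set.seed(seed)
  train <- integer(0)
  for (g in seq_along(levels(f))) {
    idx <- which(f == levels(f)[g])
    train <- c(train, idx[sample.int(length(idx), alloc[g])])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Train a tier-1 classifier
#'
#' @param features Numeric matrix (standardized tier-1 columns).
#' @param labels Class labels (tier-2 phenotype assignments).
#' @param algorithm `"forest"` (random forest, default), `"boosted"`
#'   (gradient-boosted trees) or `"margin"` (SVM with probability
#'   estimates).
#' @param seed Integer seed; training is deterministic given it.
#' @return An `hd_classifier` with `predict_class(features)` and
#'   `class_scores(features)` (rows sum to 1) plus the recorded
#'   hyperparameters.
#' @export
train_classifier <- function(features, labels,
                             algorithm = c("forest", "boosted", "margin"),
                             seed = 1L) {
  algorithm <- match.arg(algorithm)
  features <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes in training labels")
  set.seed(seed)
  if (algorithm == "forest") {
    fit <- randomForest::randomForest(features, y, ntree = 300)
    scores_fn <- function(z) stats::predict(fit, as.matrix(z), type = "prob")
    hyper <- list(ntree = 300)
  } else if (algorithm == "boosted") {
    ylev <- levels(y)
    dtrain <- xgboost::xgb.DMatrix(features, label = as.integer(y) - 1L)
    fit <- xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = nlevels(y),
                    max_depth = 4, eta = 0.3, nthread = 1, seed = seed),
      data = dtrain, nrounds = 60, verbose = 0)
    scores_fn <- function(z) {
      pr <- stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(z)))
      if (is.null(dim(pr)))
        pr <- matrix(pr, ncol = length(ylev), byrow = TRUE)
      colnames(pr) <- ylev
      pr
    }
    hyper <- list(nrounds = 60, max_depth = 4, eta = 0.3)
  } else {
    fit <- e1071::svm(features, y, probability = TRUE, kernel = "radial")
    scores_fn <- function(z) {
      pr <- attr(stats::predict(fit, as.matrix(z), probability = TRUE),
                 "probabilities")
      pr[, levels(y), drop = FALSE]
    }
    hyper <- list(kernel = "radial")
  }
  structure(
    list(algorithm = algorithm, levels = levels(y), seed = seed,
         hyperparameters = hyper,
         class_scores = scores_fn,
         predict_class = function(z) {
           sc <- scores_fn(z)
           factor(colnames(sc)[max.col(sc, ties.method = "first")],
                  levels = levels(y))
         }),
    class = "hd_classifier"
  )
}

# rank-statistic (trapezoidal ROC) AUC for one binary split
.binary_auc <- function(score, is_pos) {
  np <- sum(is_pos); nn <- sum(!is_pos)
  if (np == 0 || nn == 0) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = factor(as.integer(is_pos), levels = c(0, 1)),
                                 predictor = score, quiet = TRUE,
                                 direction = "<")))
}

#' Evaluate a classifier on labeled data
#'
#' Computes accuracy, per-class precision/recall/F1, the confusion matrix,
#' the macro one-vs-rest AUC (unweighted mean of the per-class trapezoidal
#' ROC AUCs; classes absent from the test labels are excluded with a
#' warning) and the Rand concordance between predictions and the reference
#' labels.
#'
#' @param classifier An `hd_classifier`.
#' @param features Test feature matrix.
#' @param labels Reference labels.
#' @return An `hd_classifier_report` list.
#' @export
evaluate_classifier <- function(classifier, features, labels) {
  y <- factor(labels, levels = classifier$levels)
  pred <- classifier$predict_class(features)
  scores <- classifier$class_scores(features)
  conf <- table(reference = y, predicted = factor(pred, levels = classifier$levels))
  acc <- mean(pred == y)
  per_class <- t(vapply(classifier$levels, function(cl) {
    tp <- sum(pred == cl & y == cl)
    fp <- sum(pred == cl & y != cl)
    fn <- sum(pred != cl & y == cl)
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
          else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1)
  }, numeric(3)))
  aucs <- vapply(classifier$levels, function(cl)
    .binary_auc(scores[, cl], y == cl), 0)
  if (anyNA(aucs))
    warning("classes absent from test labels excluded from macro AUC: ",
            paste(classifier$levels[is.na(aucs)], collapse = ", "))
  structure(
    list(accuracy = acc, macro_auc = mean(aucs, na.rm = TRUE),
         per_class_auc = aucs, per_class = per_class, confusion = conf,
         rand_concordance = rand_index(as.integer(pred), as.integer(y))),
    class = "hd_classifier_report"
  )
}

#' @export
print.hd_classifier_report <- function(x, ...) {
  cat("<hd_classifier_report> accuracy=", round(x$accuracy, 4),
      ", macro AUC=", round(x$macro_auc, 4),
      ", Rand concordance=", round(x$rand_concordance, 4), "\n", sep = "")
  invisible(x)
}

#' Cross-validated Rand concordance of the tier-1 classifier
#'
#' Refits the classifier per fold and reports the per-fold Rand index
#' between held-out predictions and the tier-2 labels.
#'
#' @param features Feature matrix.
#' @param labels Tier-2 labels.
#' @param folds Number of folds (default 10).
#' @param algorithm Passed to [train_classifier()].
#' @param seed Integer seed.
#' @return Numeric vector of per-fold Rand indices.
#' @export
crossval_classifier <- function(features, labels, folds = 10,
                                algorithm = "forest", seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  set.seed(seed)
  fold_of <- sample(rep(seq_len(folds), length.out = n))
  vapply(seq_len(folds), function(f) {
    hold <- which(fold_of == f)
    fit <- train_classifier(features[-hold, , drop = FALSE], labels[-hold],
                            algorithm = algorithm, seed = seed + f)
    pred <- fit$predict_class(features[hold, , drop = FALSE])
    rand_index(as.integer(pred), as.integer(factor(labels[hold], levels = fit$levels)))
  }, 0)
}

#' Derive a transparent linear scoring model (HPCS-style)
#'
#' One-vs-rest least-squares discriminants on the standardized six-parameter
#' space, with weights rounded to two decimals for hand calculation; the
#' class of a record is the argmax of the linear scores. The weights are a
#' re-derivation on the data at hand, not any previously published score
#' table.
#'
#' @param features Standardized feature matrix.
#' @param labels Class labels (>= 2 classes).
#' @return An `hd_hpcs` with `weights` (classes x (intercept + features),
#'   2-dp) and `levels`.
#' @export
derive_hpcs <- function(features, labels) {
  features <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  X <- cbind(intercept = 1, features)
  W <- t(vapply(levels(y), function(cl) {
    fit <- stats::lm.fit(X, as.numeric(y == cl))
    round(fit$coefficients, 2)
  }, numeric(ncol(X))))
  rownames(W) <- levels(y)
  structure(list(weights = W, levels = levels(y),
                 note = "re-derived linear surrogate; not a published weight table"),
            class = "hd_hpcs")
}

#' Score records with the linear surrogate
#' @param features Standardized feature matrix (or a single record vector).
#' @param model An `hd_hpcs`.
#' @return Factor of predicted classes.
#' @export
hpcs_score <- function(features, model) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  X <- cbind(1, as.matrix(features))
  sc <- X %*% t(model$weights)
  factor(model$levels[max.col(sc, ties.method = "first")],
         levels = model$levels)
}
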