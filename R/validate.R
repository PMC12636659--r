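#' Agreement statistics and clustering stability
#'
#' Pair-counting agreement between two labelings (Rand index and its
#' chance-corrected adjustment), Cohen's kappa for paired categorical
#' assignments (e.g. phenotype at two timepoints), and the two stability
#' protocols used to audit a clustering solution: bootstrap refitting and
#' k-fold cross-validated assignment.
#'
#' @name stability
NULL

#' Rand index
#'
#' Fraction of the `choose(n, 2)` unordered record pairs on which two
#' labelings agree (both together or both apart).
#'
#' @param labels_a,labels_b Equal-length label vectors (n >= 2).
#' @return Value in \[0, 1\].
#' @export
rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("length mismatch")
  n <- length(labels_a)
  if (n < 2) stop("need at least 2 records")
  tab <- table(labels_a, labels_b)
  n_pairs <- choose(n, 2)
  sum_nij2 <- sum(choose(tab, 2))
  sum_a2 <- sum(choose(rowSums(tab), 2))
  sum_b2 <- sum(choose(colSums(tab), 2))
  # agreements = together-together + apart-apart
  (n_pairs + 2 * sum_nij2 - sum_a2 - sum_b2) / n_pairs
}

#' Adjusted Rand index
#'
#' Hypergeometric chance-corrected pair agreement,
#' (Index - E\[Index\]) / (Max - E\[Index\]), from the contingency table.
#' Degenerate case (both labelings place all mass in single clusters, or
#' all records are singletons in both) is defined as 1.
#'
#' @inheritParams rand_index
#' @return Value <= 1.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("length mismatch")
  n <- length(labels_a)
  if (n < 2) stop("need at least 2 records")
  tab <- table(labels_a, labels_b)
  sum_nij2 <- sum(choose(tab, 2))
  sum_a2 <- sum(choose(rowSums(tab), 2))
  sum_b2 <- sum(choose(colSums(tab), 2))
  n2 <- choose(n, 2)
  expected <- sum_a2 * sum_b2 / n2
  maxidx <- (sum_a2 + sum_b2) / 2
  if (abs(maxidx - expected) < 1e-12) return(1)
  (sum_nij2 - expected) / (maxidx - expected)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement (p_o - p_e)/(1 - p_e) with p_e from the
#' marginal products. If both assignments are the same single category,
#' kappa is defined as 1.
#'
#' @inheritParams rand_index
#' @return Kappa value.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("length mismatch")
  lev <- union(unique(labels_a), unique(labels_b))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) {
    if (po == 1) return(1)
    stop("degenerate marginals: chance agreement is 1 but observed is not")
  }
  (po - pe) / (1 - pe)
}

#' Bootstrap stability of a clustering solution
#'
#' Per iteration: resample n rows with replacement, refit K-means with the
#' same k (fresh seeds), and compute the Rand and adjusted Rand indices
#' between the refit labeling and the reference model's labels over the
#' unique resampled records (duplicates collapse so the reference labeling
#' is well-defined per record).
#'
#' @param x Matrix the reference model was fitted on.
#' @param reference_model An `hd_kmeans` fitted on `x`.
#' @param B Number of bootstrap iterations (default 500).
#' @param seed Integer master seed.
#' @param n_init Restarts per refit (default 10).
#' @return An `hd_stability` list: `method = "bootstrap"`, `iterations`,
#'   `rand_values`, `ari_values`, `summary` (mean/sd of each).
#' @export
bootstrap_stability <- function(x, reference_model, B = 500, seed = 1L,
                                n_init = 10) {
  x <- as.matrix(x)
  ref <- reference_model$labels
  ri <- numeric(B); ari <- numeric(B)
  for (b in seq_len(B)) {
    set.seed(seed + b)
    idx <- sample(nrow(x), replace = TRUE)
    uniq <- unique(idx)
    refit <- kmeans_fit(x[idx, , drop = FALSE], reference_model$k,
                        seed = seed + 100000L + b, n_init = n_init)
    lab <- assign_clusters(refit, x[uniq, , drop = FALSE])
    ri[b] <- rand_index(lab, ref[uniq])
    ari[b] <- adjusted_rand_index(lab, ref[uniq])
  }
  structure(list(method = "bootstrap", iterations = B,
                 rand_values = ri, ari_values = ari,
                 summary = c(mean_rand = mean(ri), sd_rand = stats::sd(ri),
                             mean_ari = mean(ari), sd_ari = stats::sd(ari))),
            class = "hd_stability")
}

#' Cross-validated assignment stability
#'
#' Fits a full-data reference model, then for each of `folds` folds refits
#' K-means on the training portion and assigns the held-out records by
#' nearest centroid. Because every fold numbers its clusters arbitrarily,
#' each fold's labels are first aligned to the reference by greedy maximal
#' overlap on the training records; the aligned held-out assignments are
#' pooled over folds and the pooled ARI against the reference labels is
#' reported, together with per-fold (alignment-free) ARIs.
#'
#' @param x Numeric matrix.
#' @param k Number of clusters.
#' @param folds Number of folds (default 10).
#' @param seed Integer master seed.
#' @param n_init Restarts per fit (default 10).
#' @return An `hd_stability` list: `method = "crossval"`, per-fold
#'   `ari_values` and `rand_values`, `pooled_ari`, `reference_labels`.
#' @export
crossval_stability <- function(x, k, folds = 10, seed = 1L, n_init = 10) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (folds < 2 || n < folds) stop("need 2 <= folds <= n")
  reference <- kmeans_fit(x, k, seed = seed, n_init = n_init)
  ref <- reference$labels
  set.seed(seed)
  fold_of <- sample(rep(seq_len(folds), length.out = n))
  pooled <- integer(n)
  ri <- numeric(folds); ari <- numeric(folds)
  for (f in seq_len(folds)) {
    hold <- which(fold_of == f)
    fit <- kmeans_fit(x[-hold, , drop = FALSE], k,
                      seed = seed + 200000L + f, n_init = n_init)
    lab <- assign_clusters(fit, x[hold, , drop = FALSE])
    # align fold cluster numbering to the reference (greedy max overlap)
    map <- .align_labels(fit$labels, ref[-hold], k)
    pooled[hold] <- map[lab + 1L]
    if (length(hold) >= 2) {
      ri[f] <- rand_index(lab, ref[hold])
      ari[f] <- adjusted_rand_index(lab, ref[hold])
    } else {
      ri[f] <- NA_real_; ari[f] <- NA_real_
    }
  }
  structure(list(method = "crossval", iterations = folds,
                 rand_values = ri, ari_values = ari,
                 pooled_ari = adjusted_rand_index(pooled, ref),
                 reference_labels = ref,
                 summary = c(mean_ari = mean(ari, na.rm = TRUE),
                             pooled_ari = adjusted_rand_index(pooled, ref))),
            class = "hd_stability")
}

# greedy one-to-one map from 0-based labels `a` onto the coding of `b`
.align_labels <- function(a, b, k) {
  tab <- matrix(0, k, k)
  bb <- sort(unique(c(b, 0:(k - 1))))
  for (i in seq_along(a))
    tab[a[i] + 1L, match(b[i], bb)] <- tab[a[i] + 1L, match(b[i], bb)] + 1L
  map <- integer(k)
  used <- logical(k)
  for (step in seq_len(k)) {
    idx <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    map[idx[1]] <- bb[idx[2]]
    tab[idx[1], ] <- -1
    tab[, idx[2]] <- -1
    used[idx[2]] <- TRUE
  }
  map
}

#' @export
print.hd_stability <- function(x, ...) {
  cat("<hd_stability> ", x$method, ", ", x$iterations, " iterations\n", sep = "")
  print(round(x$summary, 4))
  invisible(x)
}
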