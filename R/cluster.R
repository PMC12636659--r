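#' Native K-means++ clustering and internal validity indices
#'
#' Phenotype discovery runs K-means with K-means++ seeding on the
#' standardized indicator matrix: Lloyd iterations (nearest-centroid
#' assignment by Euclidean distance, centroid update by arithmetic mean)
#' until membership stabilizes, best of `n_init` restarts by inertia. Model
#' quality over a k-range is summarized by inertia, mean silhouette,
#' Calinski-Harabasz and Davies-Bouldin indices, and the number of clusters
#' is chosen by a transparent policy combining the inertia elbow,
#' near-maximal silhouette and parsimony.
#'
#' @name cluster
NULL

# squared Euclidean distances rows of x -> rows of centers (n x k)
.dist2 <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, "+") - 2 * x %*% t(centers)
  d2[d2 < 0] <- 0
  d2
}

#' K-means++ initialization
#'
#' First centroid uniform over rows; each subsequent centroid sampled with
#' probability proportional to the squared distance to the nearest centroid
#' already chosen.
#'
#' @param x Numeric matrix.
#' @param k Number of centroids; must not exceed the number of distinct rows.
#' @param seed Optional integer seed (set it for a standalone reproducible
#'   draw; [kmeans_fit()] manages seeding itself).
#' @return k x p matrix of initial centroids.
#' @export
kmeanspp_init <- function(x, k, seed = NULL) {
  x <- as.matrix(x)
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) stop("k = ", k, " exceeds ", n_distinct, " distinct rows")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k == 1) return(centers)
  d2 <- .dist2(x, centers[1, , drop = FALSE])[, 1]
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      # remaining mass degenerate: pick any point not yet a centroid
      cand <- which(!duplicated(rbind(centers[seq_len(j - 1), , drop = FALSE], x))[-seq_len(j - 1)])
      centers[j, ] <- x[cand[1], ]
    } else {
      i <- sample.int(n, 1, prob = d2)
      centers[j, ] <- x[i, ]
    }
    d2 <- pmin(d2, .dist2(x, centers[j, , drop = FALSE])[, 1])
  }
  centers
}

#' Fit K-means with K-means++ restarts
#'
#' @param x Numeric matrix, all finite.
#' @param k Number of clusters.
#' @param seed Integer master seed (one restart seed derived per init).
#' @param n_init Number of independent restarts (default 10); best by
#'   inertia wins.
#' @param max_iter Lloyd iteration cap (default 300).
#' @param tol Relative inertia change declaring convergence (default 1e-6).
#' @return An `hd_kmeans`: list with `k`, `centroids`, `labels`
#'   (0-based cluster indices of the training rows), `inertia`, `seed`,
#'   `n_init`, `iterations_run`, `name_map` (filled by
#'   [name_phenotypes()]).
#' @export
kmeans_fit <- function(x, k, seed = 1L, n_init = 10, max_iter = 300,
                       tol = 1e-6) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite values in input")
  best <- NULL
  for (init in seq_len(n_init)) {
    set.seed(seed + 1000L * (init - 1L))
    centers <- kmeanspp_init(x, k)
    fit <- .lloyd(x, centers, max_iter, tol)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  structure(
    list(k = k, centroids = best$centers, labels = best$labels - 1L,
         inertia = best$inertia, seed = seed, n_init = n_init,
         iterations_run = best$iterations, name_map = NULL),
    class = "hd_kmeans"
  )
}

.lloyd <- function(x, centers, max_iter, tol) {
  n <- nrow(x)
  labels <- integer(n)
  inertia <- Inf
  for (it in seq_len(max_iter)) {
    d2 <- .dist2(x, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: reseed with the point farthest from its centroid
    for (j in seq_len(nrow(centers))) {
      if (!any(new_labels == j)) {
        far <- which.max(d2[cbind(seq_len(n), new_labels)])
        centers[j, ] <- x[far, ]
        new_labels[far] <- j
      }
    }
    new_inertia <- sum(d2[cbind(seq_len(n), new_labels)])
    converged <- identical(new_labels, labels) ||
      (is.finite(inertia) && abs(inertia - new_inertia) <= tol * inertia)
    labels <- new_labels
    for (j in seq_len(nrow(centers)))
      centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
    inertia <- new_inertia
    if (converged) break
  }
  d2 <- .dist2(x, centers)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), labels)])
  list(centers = centers, labels = labels, inertia = inertia, iterations = it)
}

#' @export
print.hd_kmeans <- function(x, ...) {
  cat("<hd_kmeans> k=", x$k, ", inertia=", signif(x$inertia, 6),
      ", sizes: ", paste(tabulate(x$labels + 1L, x$k), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' Assign records to the nearest centroid
#' @param model An `hd_kmeans`.
#' @param x Numeric matrix with matching column count.
#' @return Integer vector of 0-based cluster labels; exact distance ties go
#'   to the lowest cluster index.
#' @export
assign_clusters <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$centroids)) stop("dimension mismatch")
  d2 <- .dist2(x, model$centroids)
  max.col(-d2, ties.method = "first") - 1L
}

# validity indices --------------------------------------------------------------

#' Mean silhouette coefficient
#'
#' s(i) = (b - a)/max(a, b) with a the mean distance to the other members of
#' i's cluster and b the smallest mean distance to another cluster; members
#' of singleton clusters get s = 0.
#'
#' @param x Numeric matrix (ignored if `dmat` given).
#' @param labels Integer labels (any coding), at least two clusters.
#' @param dmat Optional precomputed `dist` object or distance matrix.
#' @return Mean silhouette over all records.
#' @export
silhouette_index <- function(x, labels, dmat = NULL) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("need at least 2 clusters")
  if (is.null(dmat)) dmat <- stats::dist(x)
  dm <- as.matrix(dmat)
  n <- nrow(dm)
  sizes <- tabulate(labels, k)
  # mean distance from each point to each cluster
  sums <- rowsum(t(dm), labels)           # k x n: sum of distances to cluster g
  meanto <- sums / sizes                  # over all members incl. self (dist 0)
  s <- numeric(n)
  for (i in seq_len(n)) {
    g <- labels[i]
    if (sizes[g] == 1) { s[i] <- 0; next }
    a <- sums[g, i] / (sizes[g] - 1)      # exclude self
    b <- min(meanto[-g, i])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Calinski-Harabasz index
#'
#' (BSS/(k-1)) / (WSS/(n-k)) with BSS the size-weighted squared deviation of
#' centroids from the grand mean and WSS the within-cluster sum of squares.
#'
#' @param x Numeric matrix.
#' @param labels Cluster labels, 2 <= k < n.
#' @return The index (`Inf` when WSS = 0 with BSS > 0).
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(factor(labels))
  k <- max(labels); n <- nrow(x)
  if (k < 2 || k >= n) stop("need 2 <= k < n")
  grand <- colMeans(x)
  bss <- 0; wss <- 0
  for (g in seq_len(k)) {
    xi <- x[labels == g, , drop = FALSE]
    cg <- colMeans(xi)
    bss <- bss + nrow(xi) * sum((cg - grand)^2)
    wss <- wss + sum(sweep(xi, 2, cg)^2)
  }
  if (wss == 0) return(if (bss > 0) Inf else 0)
  (bss / (k - 1)) / (wss / (n - k))
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst (S_i + S_j)/M_ij, where S is the mean
#' Euclidean distance of members to their centroid and M the distance
#' between centroids. Coincident centroids contribute `Inf`.
#'
#' @param x Numeric matrix.
#' @param labels Cluster labels, k >= 2, clusters non-empty.
#' @return The index.
#' @export
davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("need at least 2 clusters")
  cent <- matrix(0, k, ncol(x))
  for (g in seq_len(k))
    cent[g, ] <- colMeans(x[labels == g, , drop = FALSE])
  S <- vapply(seq_len(k), function(g) {
    xi <- x[labels == g, , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cent[g, ])^2)))
  }, 0)
  M <- sqrt(.dist2(cent, cent))
  r <- numeric(k)
  for (i in seq_len(k)) {
    rij <- (S[i] + S[-i]) / M[i, -i]
    r[i] <- max(rij)
  }
  mean(r)
}

#' Sweep candidate cluster numbers
#'
#' Fits a best-of-`n_init` K-means model for each k in `kmin:kmax` and
#' records inertia, mean silhouette, Calinski-Harabasz and Davies-Bouldin.
#' The pairwise distance matrix is computed once and shared across ks.
#'
#' @param x Standardized numeric matrix.
#' @param kmin,kmax Range of k (defaults 2 and 10).
#' @param seed Integer master seed.
#' @param n_init Restarts per k (default 10).
#' @return An `hd_cluster_quality` data.frame with one row per k and
#'   columns `k`, `inertia`, `silhouette`, `calinski_harabasz`,
#'   `davies_bouldin`; fitted models in the `models` attribute.
#' @export
k_sweep <- function(x, kmin = 2, kmax = 10, seed = 1L, n_init = 10) {
  if (kmax >= nrow(x)) stop("kmax must be smaller than n")
  dmat <- stats::dist(x)
  ks <- kmin:kmax
  models <- list()
  rows <- lapply(ks, function(k) {
    fit <- kmeans_fit(x, k, seed = seed + k, n_init = n_init)
    models[[as.character(k)]] <<- fit
    data.frame(k = k, inertia = fit$inertia,
               silhouette = silhouette_index(x, fit$labels, dmat = dmat),
               calinski_harabasz = calinski_harabasz(x, fit$labels),
               davies_bouldin = davies_bouldin(x, fit$labels))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hd_cluster_quality", "data.frame")
  attr(out, "models") <- models
  out
}

#' Choose the number of clusters
#'
#' Default policy: elbow strength
#' `e(k) = (inertia(k-1) - inertia(k)) - (inertia(k) - inertia(k+1))`
#' (defined for interior k of the sweep); the candidate set is every k whose
#' silhouette is within 10% of the maximum, plus the argmax of `e(k)`; the
#' smallest candidate wins (parsimony). Alternative policies: `"fixed"`
#' (returns `policy$k`), `"silhouette"` (argmax silhouette, smallest on
#' ties), `"elbow"` (argmax elbow strength).
#'
#' @param quality An `hd_cluster_quality` from [k_sweep()].
#' @param policy List with `type` in
#'   `c("default", "fixed", "silhouette", "elbow")` and optionally `k`.
#' @return The chosen k, with the decision rationale in the `"rationale"`
#'   attribute.
#' @export
select_k <- function(quality, policy = list(type = "default")) {
  stopifnot(nrow(quality) > 0)
  type <- if (is.null(policy$type)) "default" else policy$type
  ks <- quality$k
  if (type == "fixed")
    return(structure(policy$k, rationale = "fixed-k policy"))
  sil_best <- max(quality$silhouette)
  if (type == "silhouette") {
    k <- min(ks[quality$silhouette == sil_best])
    return(structure(k, rationale = "silhouette argmax"))
  }
  elbow <- rep(NA_real_, length(ks))
  if (length(ks) >= 3) {
    for (i in 2:(length(ks) - 1))
      elbow[i] <- (quality$inertia[i - 1] - quality$inertia[i]) -
        (quality$inertia[i] - quality$inertia[i + 1])
  }
  if (type == "elbow") {
    if (all(is.na(elbow)))
      return(structure(min(ks), rationale = "sweep too short for elbow; smallest k"))
    k <- ks[which.max(elbow)]
    return(structure(k, rationale = "elbow-strength argmax"))
  }
  cand <- ks[quality$silhouette >= 0.9 * sil_best]
  if (!all(is.na(elbow))) cand <- union(cand, ks[which.max(elbow)])
  k <- min(cand)
  structure(k, rationale = paste0(
    "candidates {", paste(sort(cand), collapse = ","),
    "} = silhouette within 10% of max (", signif(sil_best, 4),
    ") union elbow argmax; smallest chosen for parsimony"))
}
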