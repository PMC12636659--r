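#' Isolation Forest outlier screening
#'
#' Native Isolation Forest: an ensemble of random isolation trees, each
#' grown on a subsample by picking a uniformly random feature and a
#' uniformly random split point within the subsample's range, to the usual
#' height limit `ceiling(log2(subsample_size))`. The anomaly score of a
#' record is `2^(-E[h(x)]/c(psi))` where `h(x)` is the path length
#' (terminated leaves credited with the average unsuccessful-search length
#' `c(leaf size)`) and `psi` the subsample size. Records isolated after few
#' random splits score close to 1.
#'
#' @name iforest
NULL

# average unsuccessful-search path length in a BST of n nodes
.iforest_c <- function(n) {
  if (n <= 1) return(0)
  if (n == 2) return(1)
  H <- log(n - 1) + 0.5772156649015329
  2 * H - 2 * (n - 1) / n
}

# grow one isolation tree on rows `idx` of x; nested-list representation
.grow_itree <- function(x, idx, depth, limit) {
  n <- length(idx)
  if (n <= 1 || depth >= limit)
    return(list(leaf = TRUE, size = n))
  sub <- x[idx, , drop = FALSE]
  rng <- apply(sub, 2, range)
  splittable <- which(rng[2, ] > rng[1, ])
  if (length(splittable) == 0)
    return(list(leaf = TRUE, size = n))
  q <- if (length(splittable) == 1) splittable else sample(splittable, 1)
  p <- stats::runif(1, rng[1, q], rng[2, q])
  left <- idx[x[idx, q] < p]
  right <- idx[x[idx, q] >= p]
  list(leaf = FALSE, feature = q, split = p,
       left = .grow_itree(x, left, depth + 1, limit),
       right = .grow_itree(x, right, depth + 1, limit))
}

#' Fit an Isolation Forest
#'
#' @param x Numeric matrix (rows = records), all finite.
#' @param n_trees Number of trees (default 100).
#' @param subsample_size Per-tree subsample (default 256, capped at n).
#' @param seed Integer seed; the model is deterministic given it.
#' @return An `hd_iforest` with the trees and parameters.
#' @export
iforest_fit <- function(x, n_trees = 100, subsample_size = 256, seed = 1L) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite values in input")
  if (nrow(x) < 2) stop("need at least 2 records")
  psi <- min(subsample_size, nrow(x))
  limit <- ceiling(log2(psi))
  set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(t) {
    idx <- sample(nrow(x), psi)
    .grow_itree(x, idx, 0, limit)
  })
  structure(list(trees = trees, psi = psi, n_trees = n_trees, seed = seed,
                 p = ncol(x)),
            class = "hd_iforest")
}

# vectorized descent: mean path length of all rows of x in one tree
.itree_depths <- function(node, x, idx, depth, out) {
  if (node$leaf) {
    out[idx] <- depth + .iforest_c(node$size)
    return(out)
  }
  go_left <- x[idx, node$feature] < node$split
  if (any(go_left))
    out <- .itree_depths(node$left, x, idx[go_left], depth + 1, out)
  if (any(!go_left))
    out <- .itree_depths(node$right, x, idx[!go_left], depth + 1, out)
  out
}

#' Anomaly scores from a fitted Isolation Forest
#' @param model An `hd_iforest`.
#' @param x Numeric matrix with the same columns as at fit time.
#' @return Numeric vector of scores in (0, 1\].
#' @export
iforest_score <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$p) stop("column count mismatch")
  n <- nrow(x)
  depths <- matrix(0, n, model$n_trees)
  for (t in seq_along(model$trees))
    depths[, t] <- .itree_depths(model$trees[[t]], x, seq_len(n), 0, numeric(n))
  cn <- .iforest_c(model$psi)
  if (cn == 0) cn <- 1
  2^(-rowMeans(depths) / cn)
}

#' Flag the top-scoring records at a contamination level
#'
#' Flags exactly `ceiling(contamination * n)` highest-scoring records
#' (1,271 records at 0.05 give 64). Ties broken by record order (stable).
#'
#' @param scores Numeric anomaly scores.
#' @param contamination Expected outlier fraction, in (0, 0.5).
#' @return Logical mask of flagged records.
#' @export
flag_outliers <- function(scores, contamination) {
  if (contamination <= 0 || contamination >= 0.5)
    stop("contamination must lie in (0, 0.5)")
  n <- length(scores)
  m <- ceiling(contamination * n)
  ord <- order(-scores, seq_len(n))
  mask <- rep(FALSE, n)
  mask[ord[seq_len(m)]] <- TRUE
  mask
}

#' Exclude flagged records from a cohort
#' @param table An `hd_cohort`.
#' @param mask Logical vector, length n; `TRUE` rows are dropped.
#' @param scores Optional scores recorded in the exclusion log.
#' @return The reduced `hd_cohort`, with an `exclusion_log` attribute
#'   (data.frame id/score/flagged).
#' @export
exclude <- function(table, mask, scores = NULL) {
  stopifnot(length(mask) == nrow(table$values))
  if (all(mask)) warning("all records flagged; returning empty table")
  out <- cohort_subset(table, !mask)
  attr(out, "exclusion_log") <- data.frame(
    id = table$ids,
    score = if (is.null(scores)) NA_real_ else scores,
    flagged = mask
  )
  out
}
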