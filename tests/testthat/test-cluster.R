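test_that("k-means++ seeding spreads initial centroids by squared distance", {
  x <- rbind(c(0, 0), c(0.1, 0), c(100, 100), c(100.1, 100))
  same_pair <- 0
  for (s in 1:200) {
    cent <- kmeanspp_init(x, 2, seed = s)
    d <- as.matrix(dist(rbind(cent, x)))[1:2, 3:6]
    pair_of <- apply(d, 1, function(r) if (which.min(r) <= 2) 1 else 2)
    if (pair_of[1] == pair_of[2]) same_pair <- same_pair + 1
  }
  expect_lt(same_pair / 200, 0.05)
  # k = n: every distinct point becomes a centroid
  cent <- kmeanspp_init(x, 4, seed = 1)
  expect_equal(dim(cent), c(4L, 2L))
  expect_equal(nrow(unique(cent)), 4)
  expect_error(kmeanspp_init(rbind(c(1, 1), c(1, 1)), 2), "distinct")
  expect_equal(nrow(kmeanspp_init(x, 1, seed = 2)), 1)
})

test_that("Lloyd iterations find the exact optimum on worked examples", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  fit <- kmeans_fit(x, 2, seed = 1)
  expect_equal(sort(fit$centroids[, 1]), c(0.5, 10.5))
  expect_equal(fit$inertia, 1.0)
  expect_equal(kmeans_fit(x, 4, seed = 1)$inertia, 0)
  dup <- matrix(rep(c(3, 3), 5), ncol = 2, byrow = TRUE)
  expect_equal(kmeans_fit(dup, 1, seed = 1)$centroids[1, ], c(3, 3))
  expect_error(kmeans_fit(matrix(c(1, NA), 2, 1), 1), "non-finite")
})

test_that("k-means equals the brute-force optimal partition on small data", {
  for (case in 1:12) {
    set.seed(case)
    n <- sample(4:8, 1)
    k <- sample(2:3, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    fit <- kmeans_fit(x, k, seed = case, n_init = 20)
    expect_equal(fit$inertia, brute_force_inertia(x, k), tolerance = 1e-8,
                 info = paste("case", case))
  }
})

test_that("assignment uses nearest centroid with lowest-index ties", {
  model <- kmeans_fit(matrix(c(0, 0, 10, 10), ncol = 1), 2, seed = 1)
  lab <- assign_clusters(model, matrix(5, 1, 1))  # equidistant
  expect_equal(lab, 0L)  # tie goes to the lowest cluster index
  expect_error(assign_clusters(model, matrix(1, 1, 2)), "dimension")
  # training assignment reproduces stored inertia
  x <- matrix(rnorm(60), 30, 2)
  m <- kmeans_fit(x, 3, seed = 2)
  lab2 <- assign_clusters(m, x)
  inertia <- sum((x - m$centroids[lab2 + 1, ])^2)
  expect_equal(inertia, m$inertia, tolerance = 1e-8)
})

test_that("validity indices match hand-computed 4-point values", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  lab <- c(0, 0, 1, 1)
  expect_equal(silhouette_index(x, lab), 0.8997, tolerance = 1e-4)
  expect_equal(calinski_harabasz(x, lab), 200.0)
  expect_equal(davies_bouldin(x, lab), 0.1)
  expect_error(silhouette_index(x, rep(0, 4)), "2 clusters")
  expect_error(calinski_harabasz(x, 0:3), "k < n")
  # degenerate spreads
  y <- matrix(c(0, 0, 5, 5), ncol = 1)
  expect_equal(davies_bouldin(y, lab), 0)
  expect_equal(calinski_harabasz(y, lab), Inf)
})

test_that("silhouette agrees with the cluster package on random data", {
  skip_if_not_installed("cluster")
  set.seed(9)
  x <- matrix(rnorm(80), 40, 2)
  lab <- sample(1:3, 40, replace = TRUE)
  ours <- silhouette_index(x, lab)
  ref <- mean(cluster::silhouette(lab, dist(x))[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("random labels give near-unit Calinski-Harabasz in expectation", {
  set.seed(10)
  vals <- replicate(30, {
    x <- matrix(rnorm(400), 200, 2)
    calinski_harabasz(x, sample(1:3, 200, replace = TRUE))
  })
  expect_equal(mean(vals), 1, tolerance = 0.25)
})

test_that("the k sweep resolves three symmetric well-separated components", {
  # equilateral three-blob configuration: the canonical case in which the
  # silhouette curve must peak at the true k
  set.seed(40)
  centers <- rbind(c(0, 0), c(4, 0), c(2, 2 * sqrt(3)))
  x <- centers[rep(1:3, each = 40), ] + matrix(rnorm(240, 0, 0.2), 120, 2)
  truth <- rep(0:2, each = 40)
  q <- k_sweep(x, 2, 7, seed = 42, n_init = 5)
  expect_equal(nrow(q), 6)
  expect_true(all(diff(q$inertia) <= 1e-8))
  expect_true(all(q$silhouette >= -1 & q$silhouette <= 1))
  expect_true(all(q$calinski_harabasz > 0))
  expect_equal(q$k[which.max(q$silhouette)], 3)
  k <- select_k(q)
  expect_equal(as.numeric(k), 3)
  expect_match(attr(k, "rationale"), "parsimony")
  expect_equal(adjusted_rand_index(attr(q, "models")[["3"]]$labels, truth), 1)
})

test_that("the k sweep recovers the phenotype mixture when groups are tight", {
  lab <- generate(separated_spec(seed = 41))
  std <- fit_preprocessor(lab$table)$standardized
  q <- k_sweep(std, 2, 5, seed = 42, n_init = 5)
  expect_true(all(diff(q$inertia) <= 1e-8))
  m <- attr(q, "models")[["3"]]
  expect_gt(adjusted_rand_index(m$labels, lab$true_labels), 0.95)
  # the drop in inertia flattens sharply beyond the true k
  drops <- -diff(q$inertia)
  expect_gt(drops[1], 3 * drops[2])
})

test_that("the k-selection policy is transparent and overridable", {
  q <- data.frame(k = 2:6,
                  inertia = 1000 * 0.5^(0:4),     # geometric decay
                  silhouette = rep(0.5, 5),
                  calinski_harabasz = 1, davies_bouldin = 1)
  class(q) <- c("hd_cluster_quality", "data.frame")
  expect_equal(as.numeric(select_k(q)), 2)  # flat silhouette: parsimony
  expect_equal(as.numeric(select_k(q, list(type = "fixed", k = 4))), 4)
  q$silhouette <- c(0.2, 0.6, 0.3, 0.2, 0.1)
  expect_equal(as.numeric(select_k(q, list(type = "silhouette"))), 3)
})
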