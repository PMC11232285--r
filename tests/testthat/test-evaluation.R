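two_blobs <- function(n_per = 30, sep = 10, d = 3, seed = 1) {
  set.seed(seed)
  pts <- rbind(matrix(rnorm(n_per * d), n_per, d),
               matrix(rnorm(n_per * d, mean = sep), n_per, d))
  list(points = pts, labels = rep(c("A", "B"), each = n_per))
}

test_that("kNN purity separates blobs and matches the brute-force definition", {
  bl <- two_blobs(50, sep = 10)
  expect_equal(knn_purity(bl$points, bl$labels, k = 10), 1)
  # random labels within one blob sit near the label frequency
  set.seed(3)
  pts <- matrix(rnorm(400 * 2), 400, 2)
  labs <- sample(rep(c("A", "B"), 200))
  expect_lt(abs(knn_purity(pts, labs, k = 10) - 0.5), 0.06)
  # exact agreement with the naive computation on small instances
  for (s in 1:5) {
    set.seed(s)
    p <- matrix(rnorm(25 * 2), 25, 2)
    l <- sample(c("x", "y", "z"), 25, replace = TRUE)
    expect_equal(knn_purity(p, l, k = 4), oracle_purity(p, l, k = 4))
  }
  expect_error(knn_purity(matrix(0, 3, 2), c(1, 2, 3), k = 3), "smaller")
})

test_that("a fully mismatched neighbourhood contributes zero purity", {
  pts <- rbind(c(0, 0), matrix(rnorm(10 * 2, 0, 0.1), 10, 2))
  labs <- c("X", rep("Y", 10))
  # the X point's neighbours are all Y; its contribution is 0
  per_point_mean <- knn_purity(pts, labs, k = 10)
  expect_equal(per_point_mean, (0 + 10 * (9 / 10)) / 11)
})

test_that("Gaussian-mixture clustering recovers separated blobs deterministically", {
  bl <- two_blobs(40, sep = 8, seed = 5)
  a1 <- cluster_gmm(bl$points, 2, seed = 1)
  a2 <- cluster_gmm(bl$points, 2, seed = 1)
  expect_identical(a1, a2)
  expect_equal(ari(bl$labels, a1), 1)
  # permutation of the input points permutes assignments consistently
  perm <- sample(nrow(bl$points))
  a3 <- cluster_gmm(bl$points[perm, ], 2, seed = 1)
  expect_equal(ari(a1[perm], a3), 1)
})

test_that("NMI follows its entropy-normalized definition", {
  a <- c(1, 1, 2, 2); b <- c(2, 2, 1, 1)
  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(a, b), 1)  # permutation invariance
  expect_warning(v <- nmi(c(1, 1), c(1, 1)), "single class")
  expect_equal(v, 1)
  for (s in 1:5) {
    set.seed(s)
    x <- sample(1:3, 40, replace = TRUE)
    y <- sample(1:2, 40, replace = TRUE)
    expect_equal(nmi(x, y), oracle_nmi(x, y), tolerance = 1e-10)
  }
  # independent labelings at large n drift to zero
  set.seed(9)
  x <- sample(1:2, 1000, replace = TRUE)
  y <- sample(1:2, 1000, replace = TRUE)
  expect_lt(nmi(x, y), 0.02)
})

test_that("ARI matches exhaustive pair counting", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(ari(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(ari(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               oracle_ari(c(1, 1, 2, 2), c(1, 2, 1, 2)))
  for (s in 1:5) {
    set.seed(100 + s)
    x <- sample(1:3, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(ari(x, y), oracle_ari(x, y), tolerance = 1e-12)
  }
  # random labelings have expected ARI about 0
  set.seed(12)
  m <- mean(replicate(40, ari(sample(1:2, 100, replace = TRUE),
                              sample(1:2, 100, replace = TRUE))))
  expect_lt(abs(m), 0.02)
})

test_that("silhouette follows the (b - a) / max(a, b) definition", {
  bl <- two_blobs(30, sep = 50, seed = 7)
  cl <- rep(1:2, each = 30)
  expect_gt(silhouette_index(bl$points, cl), 0.95)
  # coincident points in 2 clusters: a = b = 0 contributes 0
  pts0 <- matrix(0, 6, 2)
  expect_equal(silhouette_index(pts0, rep(1:2, 3)), 0)
  # colinear 2/2 hand case and random checks against the naive loop
  pts <- matrix(c(0, 1, 10, 11), 4, 1)
  expect_equal(silhouette_index(pts, c(1, 1, 2, 2)),
               oracle_silhouette(pts, c(1, 1, 2, 2)), tolerance = 1e-12)
  for (s in 1:5) {
    set.seed(200 + s)
    p <- matrix(rnorm(30 * 2), 30, 2)
    cl <- sample(1:3, 30, replace = TRUE)
    expect_equal(silhouette_index(p, cl), oracle_silhouette(p, cl),
                 tolerance = 1e-10)
  }
  expect_error(silhouette_index(matrix(rnorm(10), 5, 2), rep(1, 5)),
               "2 clusters")
})

test_that("Dunn index is the separation/diameter ratio and scale invariant", {
  pts <- matrix(c(0, 1, 5, 6, 0, 0, 0, 0), 4, 2)
  cl <- c(1, 1, 2, 2)
  expect_equal(dunn_index(pts, cl), 4)
  expect_equal(dunn_index(pts * 3.7, cl), 4)
  for (s in 1:5) {
    set.seed(300 + s)
    p <- matrix(rnorm(24 * 2), 24, 2)
    cl <- rep(1:3, each = 8)
    expect_equal(dunn_index(p, cl), oracle_dunn(p, cl), tolerance = 1e-12)
  }
  expect_error(dunn_index(matrix(0, 4, 2), c(1, 1, 2, 2)), "degenerate")
})

test_that("reconstruction error obeys its MSE / R-squared identities", {
  set.seed(4)
  real <- matrix(rnorm(50), 10, 5)
  expect_equal(reconstruction_error(real, real), list(mse = 0, r2 = 1))
  shifted <- reconstruction_error(real, real + 1)
  expect_equal(shifted$mse, 1)
  pooled <- matrix(mean(real), 10, 5)
  expect_equal(reconstruction_error(real, pooled)$r2, 0)
  expect_error(reconstruction_error(real, real[1:5, ]), "shape")
})

test_that("condition evaluation reports NA errors without reconstructions", {
  sim <- small_sim(seed = 13, n = 60, g = 8, informative = 3, shift = 3)
  rep_none <- evaluate_condition(sim$a, sim$b, k = 5, seed = 1)
  expect_identical(rep_none$condition, "none")
  expect_true(is.na(rep_none$mse) && is.na(rep_none$r2))
  expect_gt(rep_none$knn_purity, 0.9)   # well-separated domains
  # oracle-map transfer looks like the target domain: metrics stay high
  tr_ab <- known_map_transfer(sim$ground_truth, sim$a, "ab")
  tr_ba <- known_map_transfer(sim$ground_truth, sim$b, "ba")
  m <- make_identity_model(colnames(sim$a$expression))
  rec <- list(a = reconstruct_domain(m, sim$a, "aba"),
              b = reconstruct_domain(m, sim$b, "bab"))
  rep_model <- evaluate_condition(sim$a, sim$b,
                                  generated = list(ab = tr_ab, ba = tr_ba),
                                  reconstructed = rec, k = 5, seed = 1)
  expect_identical(rep_model$condition, "model")
  expect_gt(rep_model$knn_purity, 0.9)
  expect_gt(rep_model$ari, 0.8)
  # identity reconstruction has zero error and perfect R-squared
  expect_equal(rep_model$mse, 0, tolerance = 1e-10)
  expect_equal(rep_model$r2, 1, tolerance = 1e-10)
})
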