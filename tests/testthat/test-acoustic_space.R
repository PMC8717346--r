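two_class_data <- function(sep, n = 100, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             matrix(rnorm(2 * n, mean = sep), n, 2))
  list(X = as.data.frame(X),
       y = rep(c("female", "male"), each = n))
}

test_that("supervised RF separates separable classes and not permuted ones", {
  d <- two_class_data(20)
  rep1 <- fit_supervised_rf(d$X, d$y, rf_params(n_trees = 500, seed = 2))
  expect_lt(rep1$oob_total_error, 0.02)
  expect_true(all(rep1$per_class_correct > 0.95))

  set.seed(3)
  yp <- sample(d$y)
  rep2 <- fit_supervised_rf(d$X, yp, rf_params(n_trees = 500, seed = 4))
  expect_gt(rep2$oob_total_error, 0.43)
  expect_lt(rep2$oob_total_error, 0.57)
})

test_that("supervised RF validates inputs and is seed-deterministic", {
  d <- two_class_data(2, n = 30)
  expect_error(fit_supervised_rf(d$X, rep("male", 60)), "two classes")
  expect_error(fit_supervised_rf(d$X, c("male", rep("female", 59))),
               ">= 2 samples")
  r1 <- fit_supervised_rf(d$X, d$y, rf_params(n_trees = 200, seed = 7))
  r2 <- fit_supervised_rf(d$X, d$y, rf_params(n_trees = 200, seed = 7))
  expect_identical(r1$oob_total_error, r2$oob_total_error)
  expect_identical(r1$importance, r2$importance)

  # constant feature is allowed and earns ~zero importance
  X3 <- cbind(d$X, konst = 1)
  r3 <- fit_supervised_rf(X3, d$y, rf_params(n_trees = 200, seed = 8))
  expect_lt(r3$importance[["konst"]], min(r3$importance[c("V1", "V2")]))
})

test_that("duplicated features share importance without inflating it", {
  d <- two_class_data(3, n = 80, seed = 5)
  single <- fit_supervised_rf(d$X["V1"], d$y,
                              rf_params(n_trees = 400, mtry = 1, seed = 6))
  dup <- fit_supervised_rf(data.frame(a = d$X$V1, b = d$X$V1), d$y,
                           rf_params(n_trees = 400, mtry = 1, seed = 6))
  tot_single <- sum(single$importance)
  tot_dup <- sum(dup$importance)
  expect_gt(tot_dup / tot_single, 0.5)
  expect_lt(tot_dup / tot_single, 2)
})

test_that("oob error is stable across seeds at high tree counts", {
  d <- two_class_data(1.5, n = 60, seed = 9)
  e1 <- fit_supervised_rf(d$X, d$y, rf_params(n_trees = 5000, seed = 1))
  e2 <- fit_supervised_rf(d$X, d$y, rf_params(n_trees = 5000, seed = 2))
  expect_lt(abs(e1$oob_total_error - e2$oob_total_error), 0.03)
})

test_that("unsupervised proximity is a valid similarity with honest structure", {
  set.seed(12)
  X <- rbind(matrix(rnorm(100, 0), 25, 4), matrix(rnorm(100, 4), 25, 4))
  pr <- fit_unsupervised_rf_proximity(
    as.data.frame(X), rf_params(800, mtry = 2, mode = "unsupervised", seed = 3))
  P <- pr$P
  expect_equal(P, t(P))
  expect_equal(unname(diag(P)), rep(1, 50))
  expect_true(all(P >= 0 & P <= 1))
  grp <- rep(1:2, each = 25)
  within <- mean(P[grp == 1, grp == 1][upper.tri(diag(25))])
  between <- mean(P[grp == 1, grp == 2])
  expect_gt(within, between)
  expect_error(fit_unsupervised_rf_proximity(as.data.frame(X[, 1, drop = FALSE])),
               ">= 2 features")
  expect_error(fit_unsupervised_rf_proximity(as.data.frame(X[1:5, ])),
               ">= 10 samples")
})

test_that("proximity row means fall when a point is isolated", {
  set.seed(13)
  X <- matrix(rnorm(80), 20, 4)
  pr1 <- fit_unsupervised_rf_proximity(
    as.data.frame(X), rf_params(600, mtry = 2, mode = "unsupervised", seed = 5))
  X2 <- X; X2[1, ] <- X2[1, ] + 25
  pr2 <- fit_unsupervised_rf_proximity(
    as.data.frame(X2), rf_params(600, mtry = 2, mode = "unsupervised", seed = 5))
  m1 <- mean(pr1$P[1, -1]); m2 <- mean(pr2$P[1, -1])
  expect_lt(m2, m1)
})

test_that("proximity converts to a proper dissimilarity", {
  P <- diag(5)
  D <- proximity_to_distance(P)
  expect_equal(unname(diag(D)), rep(0, 5))
  expect_equal(unique(D[upper.tri(D)]), 1)
  expect_equal(proximity_to_distance(matrix(1, 4, 4)), matrix(0, 4, 4))
})

test_that("classical MDS recovers planted geometry", {
  set.seed(14)
  X <- matrix(rnorm(60), 30, 2)
  D <- as.matrix(dist(X))
  emb <- classical_mds(D, k = 2)
  expect_equal(ncol(emb$coords), 2)
  expect_lt(procrustes_rms(X, emb$coords), 1e-8)
  # distances reproduced at the intrinsic dimension
  expect_lt(max(abs(as.matrix(dist(emb$coords)) - D)), 1e-6)
  # eigenvalues descending
  expect_true(all(diff(emb$eigenvalues[1:2]) <= 0))

  # three equidistant points: an equilateral triangle, equal eigenvalues
  D3 <- matrix(1, 3, 3); diag(D3) <- 0
  e3 <- classical_mds(D3, k = 2)
  expect_equal(e3$eigenvalues[1], e3$eigenvalues[2], tolerance = 1e-10)
  expect_equal(as.numeric(dist(e3$coords)), rep(1, 3), tolerance = 1e-10)

  # all-zero dissimilarities: all coordinates zero, with a warning
  expect_warning(e0 <- classical_mds(matrix(0, 5, 5), k = 2), "positive")
  expect_equal(unname(e0$coords), matrix(0, 5, 2))
})

test_that("NMDS reaches low stress on metric input and respects nesting", {
  set.seed(15)
  X <- matrix(rnorm(50), 25, 2)
  D <- as.matrix(dist(X))
  e2 <- kruskal_nmds(D, k = 2, seed = 1)
  expect_lt(e2$stress, 0.01)
  e3 <- kruskal_nmds(D, k = 3, seed = 1)
  expect_lte(e3$stress, e2$stress + 1e-8)
  expect_error(kruskal_nmds(matrix(0, 6, 6)), "identical")
})

test_that("NMDS is invariant to monotone transforms of the dissimilarities", {
  set.seed(16)
  X <- matrix(rnorm(44), 22, 2)
  D <- as.matrix(dist(X))
  a <- kruskal_nmds(D, k = 2, seed = 2)
  b <- kruskal_nmds(D^3, k = 2, seed = 2)
  expect_lt(abs(a$stress - b$stress), 1e-3)
  # same configuration up to rigid transform and scale
  ca <- scale(a$coords, scale = FALSE); cb <- scale(b$coords, scale = FALSE)
  ca <- ca / sqrt(sum(ca^2));           cb <- cb / sqrt(sum(cb^2))
  expect_lt(procrustes_rms(ca, cb), 0.01)
})

test_that("NMDS tolerates duplicate points via primary tie handling", {
  set.seed(17)
  X <- matrix(rnorm(40), 20, 2)
  X[2, ] <- X[1, ]                      # duplicated point, zero distance
  e <- kruskal_nmds(as.matrix(dist(X)), k = 2, seed = 3)
  expect_true(is.finite(e$stress))
  expect_lt(sqrt(sum((e$coords[1, ] - e$coords[2, ])^2)), 0.1)
})
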