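unit_sq <- function(dx = 0, dy = 0, s = 1)
  cbind(c(0, s, s, 0) + dx, c(0, 0, s, s) + dy)

test_that("dimorphism metrics on analytic configurations", {
  # identical sets: full overlap, no distance, no size difference
  m <- dimorphism_metrics(unit_sq(), unit_sq())
  expect_equal(unname(m), c(1, 0, 0), tolerance = 1e-12)

  # unit squares offset by 0.5: intersection 0.5 over union 1.5
  m2 <- dimorphism_metrics(unit_sq(), unit_sq(0.5))
  expect_equal(m2[["overlap_prop"]], 1 / 3, tolerance = 1e-12)
  expect_equal(m2[["area_size_difference"]], 0, tolerance = 1e-12)

  # disjoint distant squares
  m3 <- dimorphism_metrics(unit_sq(), unit_sq(10))
  expect_equal(m3[["overlap_prop"]], 0)

  # congruent shifted polygons have equal areas
  by_sex <- acoustic_area_by_sex(rbind(unit_sq(), unit_sq(10)),
                                 rep(c("male", "female"), each = 4),
                                 retain = 1)
  expect_equal(by_sex$male$area, by_sex$female$area, tolerance = 1e-12)
  expect_error(acoustic_area_by_sex(unit_sq(), rep("male", 4)), "both sexes")
})

test_that("degenerate polygons follow the documented conventions", {
  pt <- matrix(rep(c(0.5, 0.5), 3), 3, 2, byrow = TRUE)
  both <- dimorphism_metrics(pt, pt + 1)
  expect_equal(as.numeric(both), c(0, 0, 0))
  expect_equal(attr(both, "degenerate"), "both")
  one <- dimorphism_metrics(pt, unit_sq())
  expect_equal(one[["overlap_prop"]], 0)
  expect_equal(one[["area_size_difference"]], 1)
})

test_that("metrics are symmetric in sex labels and affine-stable", {
  set.seed(21)
  a <- matrix(rnorm(40), 20, 2)
  b <- matrix(rnorm(40, 0.5), 20, 2)
  m_ab <- dimorphism_metrics(a, b)
  m_ba <- dimorphism_metrics(b, a)
  expect_equal(m_ab[["overlap_prop"]], m_ba[["overlap_prop"]],
               tolerance = 1e-10)
  expect_equal(m_ab[["centroid_distance"]], m_ba[["centroid_distance"]],
               tolerance = 1e-10)
  expect_equal(m_ab[["area_size_difference"]], m_ba[["area_size_difference"]],
               tolerance = 1e-10)

  # translation and axis-wise scaling wash out after the pooled z-transform
  tf <- function(p) cbind(3 * p[, 1] + 10, 0.25 * p[, 2] - 4)
  expect_equal(unname(dimorphism_metrics(tf(a), tf(b))), unname(m_ab),
               tolerance = 1e-8)
})

test_that("balanced subsampling: equal sizes reduce to the full data", {
  set.seed(5)
  a <- matrix(rnorm(30), 15, 2)
  b <- matrix(rnorm(30, 1), 15, 2)
  res <- balanced_subsample_dimorphism(a, b, n_iter = 100, seed = 9)
  expect_equal(unname(res$metrics), unname(dimorphism_metrics(a, b)),
               tolerance = 1e-12)
  expect_equal(apply(res$per_iteration, 2, stats::var), rep(0, 3),
               ignore_attr = TRUE)
})

test_that("balanced subsampling is deterministic given its seed", {
  set.seed(6)
  a <- matrix(rnorm(80), 40, 2)
  b <- matrix(rnorm(24, 0.5), 12, 2)
  r1 <- balanced_subsample_dimorphism(a, b, n_iter = 50, seed = 123)
  r2 <- balanced_subsample_dimorphism(a, b, n_iter = 50, seed = 123)
  expect_identical(r1$per_iteration, r2$per_iteration)
  r3 <- balanced_subsample_dimorphism(a, b, n_iter = 50, seed = 124)
  expect_false(identical(r1$per_iteration, r3$per_iteration))
  expect_error(balanced_subsample_dimorphism(a, b, n_iter = 0), "n_iter")
})

test_that("subsampled means converge with iteration count", {
  set.seed(7)
  a <- matrix(rnorm(400), 200, 2)
  b <- matrix(rnorm(40, 0.3), 20, 2)
  r100 <- balanced_subsample_dimorphism(a, b, n_iter = 100, seed = 1)
  r1000 <- balanced_subsample_dimorphism(a, b, n_iter = 1000, seed = 2)
  se <- stats::sd(r100$per_iteration[, "overlap_prop"]) / sqrt(100)
  expect_lt(abs(r100$metrics[["overlap_prop"]] -
                r1000$metrics[["overlap_prop"]]), 3 * se)
})

test_that("element diversity scores equal the hull-area oracle", {
  # coincident elements: zero diversity
  co <- matrix(rep(c(1, 2), 4), 4, 2, byrow = TRUE)
  sc <- element_diversity_scores(co, rep("s1", 4), retain = 1)
  expect_equal(as.numeric(sc), 0)

  # halved configuration has a quarter of the area
  emb <- rbind(unit_sq(), unit_sq() / 2)
  ids <- rep(c("big", "small"), each = 4)
  sc2 <- element_diversity_scores(emb, ids, retain = 1)
  expect_equal(unname(sc2["big"] / sc2["small"]), 4, tolerance = 1e-12)

  # random songs match the oracle exactly
  set.seed(8)
  coords <- matrix(rnorm(200), 100, 2)
  ids3 <- rep(sprintf("s%d", 1:5), each = 20)
  sc3 <- element_diversity_scores(coords, ids3, retain = 0.95)
  for (s in unique(ids3)) {
    expect_equal(sc3[[s]], oracle_mcp_area(coords[ids3 == s, ], 0.95),
                 tolerance = 1e-11)
  }
  expect_error(element_diversity_scores(coords, ids3[-1]), "map every")
})

test_that("planted sex shifts move overlap down and distance up", {
  set.seed(31)
  shifts <- seq(0, 4, length.out = 5)
  res <- t(vapply(shifts, function(s) {
    ov <- dv <- numeric(8)
    for (r in 1:8) {
      a <- matrix(rnorm(60), 30, 2)
      b <- matrix(rnorm(60, s), 30, 2)
      m <- dimorphism_metrics(a, b)
      ov[r] <- m[["overlap_prop"]]; dv[r] <- m[["centroid_distance"]]
    }
    c(mean(ov), mean(dv))
  }, numeric(2)))
  expect_gt(stats::cor(shifts, res[, 2], method = "spearman"), 0.9)
  expect_lt(stats::cor(shifts, res[, 1], method = "spearman"), -0.9)
})
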