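small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_species = 5, populations_per_species = rep(1, 5),
         individuals_per_population = 4, songs_per_individual = 2,
         elements_per_song = c(3, 7)),
    list(...))
  do.call(sim_config, args)
}

test_that("simulated trees are ultrametric, labelled, reproducible", {
  tr <- simulate_tree(9, seed = 3)
  expect_equal(length(tr$tip.label), 9)
  expect_equal(tr$tip.label, sprintf("species_%02d", 1:9))
  depths <- ape::node.depth.edgelength(tr)[1:9]
  expect_lt(diff(range(depths)), 1e-9)
  expect_equal(max(depths), 1, tolerance = 1e-9)
  expect_identical(ape::write.tree(simulate_tree(9, seed = 3)),
                   ape::write.tree(tr))
  tr2 <- simulate_tree(2, seed = 1)
  expect_equal(sort(ape::node.depth.edgelength(tr2)[1:2]), c(1, 1))
})

test_that("generated datasets satisfy the element-table contract", {
  d <- simulate_dataset(small_cfg())
  el <- d$elements
  expect_s3_class(el, "element_table")
  expect_true(all(el$end_time > el$start_time))
  expect_true(all(el$freq_95 > el$freq_5))
  expect_length(feature_names(el), 22)
  key <- unique(el[, c("song_id", "individual_id", "population", "species",
                       "sex")])
  expect_false(anyDuplicated(key$song_id) > 0)
  expect_true(all(table(el$song_id) >= 1))
  # life-history table: one row per population, latitude always finite
  lh <- d$lifehistory
  expect_equal(nrow(lh), 5)
  expect_true(all(is.finite(lh$latitude)))
  expect_true(all(stats::na.omit(lh$epp) >= 0 & stats::na.omit(lh$epp) <= 1))
})

test_that("the full default preset mirrors the study shape", {
  cfg <- sim_config(seed = 2)
  expect_equal(cfg$n_species, 9)
  expect_equal(sum(cfg$populations_per_species), 15)
  expect_equal(sort(cfg$populations_per_species, decreasing = TRUE)[1:3],
               c(5, 2, 2))
})

test_that("the generator is deterministic and validates its config", {
  d1 <- simulate_dataset(small_cfg(seed = 7))
  d2 <- simulate_dataset(small_cfg(seed = 7))
  expect_identical(as.data.frame(d1$elements), as.data.frame(d2$elements))
  expect_identical(as.data.frame(d1$lifehistory),
                   as.data.frame(d2$lifehistory))
  d3 <- simulate_dataset(small_cfg(seed = 8))
  expect_false(identical(as.data.frame(d1$elements),
                         as.data.frame(d3$elements)))
  expect_error(sim_config(elements_per_song = c(8, 3)), "elements_per_song")
})

test_that("null datasets carry no sex signal, planted ones plenty", {
  null <- simulate_null_dataset(small_cfg(seed = 9,
                                          individuals_per_population = 8,
                                          songs_per_individual = 3))
  el <- as.data.frame(null$elements)
  fn <- feature_names(null$elements)
  for (f in fn[1:6]) {
    male <- el[[f]][el$sex == "male"]; fem <- el[[f]][el$sex == "female"]
    se <- sqrt(stats::var(male) / length(male) + stats::var(fem) / length(fem))
    expect_lt(abs(mean(male) - mean(fem)), 3 * se + 1e-12)
  }

  strong <- simulate_dataset(small_cfg(
    seed = 10, individuals_per_population = 8,
    feature_sex_effect = c(5, 5, 5, rep(0, 19))))
  els <- as.data.frame(strong$elements)
  rep <- fit_supervised_rf(els[, feature_names(strong$elements)], els$sex,
                           rf_params(n_trees = 300, mtry = 5, seed = 1))
  expect_lt(rep$oob_total_error, 0.10)
})

test_that("species means converge to the Brownian covariance", {
  tr <- simulate_tree(6, seed = 11)
  C <- phylo_vcv(tr)
  reps <- vapply(1:1000, function(r) {
    songspace:::sim_species_means(tr, 1, bm_sigma2 = 0.7, seed = r)[, 1]
  }, numeric(6))
  S <- stats::cov(t(reps))
  expect_lt(norm(S - 0.7 * C, "F") / norm(0.7 * C, "F"), 0.15)
})

test_that("planted gap slopes appear in the derived song durations", {
  cfg <- sim_config(seed = 13, individuals_per_population = 8,
                    songs_per_individual = 3,
                    lifehistory_slopes = c(male_survival = 0.6),
                    missing_rate = 0)
  d <- simulate_dataset(cfg)
  songs <- derive_song_table(d$elements)
  songs$logdur <- log(songs$song_duration)
  gap <- vapply(split(songs, songs$population), function(s) {
    mean(s$logdur[s$sex == "male"]) - mean(s$logdur[s$sex == "female"])
  }, numeric(1))
  z <- as.numeric(scale(d$lifehistory$male_survival))
  slope <- coef(stats::lm(gap ~ z))[["z"]]
  expect_equal(slope, 0.6, tolerance = 0.25)
})
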