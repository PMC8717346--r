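test_that("priors and chain specs validate their fields", {
  p <- prior_spec()
  expect_equal(p$residual, list(V = 1, nu = 0.002))
  expect_equal(p$random, list(V = 1, nu = 1, alpha.mu = 0, alpha.V = 625))
  ch <- chain_preset("elaboration")
  expect_equal(c(ch$n_iter, ch$burn_in, ch$thin), c(300000, 300, 30))
  ch2 <- chain_preset("sex_differences")
  expect_equal(c(ch2$n_iter, ch2$burn_in, ch2$thin), c(1750000, 300, 15))
  ch3 <- chain_preset("dimorphism")
  expect_equal(c(ch3$n_iter, ch3$burn_in, ch3$thin), c(500000, 500, 30))
  expect_error(chain_spec(100, 200, 1), "n_iter")
})

test_that("with no random effects the posterior matches least squares", {
  set.seed(41)
  n <- 500
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 1 + 2 * d$x1 - 0.5 * d$x2 + rnorm(n)
  fit <- phylo_mmm(y ~ x1 + x2, d, chain = chain_spec(12000, 2000, 5, seed = 2))
  ols <- coef(stats::lm(y ~ x1 + x2, d))
  s <- summary(fit)$solutions
  for (j in seq_len(nrow(s))) {
    mcse <- stats::sd(fit$Sol[, j]) / sqrt(s$ess[j])
    expect_lt(abs(s$post_mean[j] - ols[[j]]), 3 * mcse + 2e-3)
  }
})

test_that("chains are bit-identical given the seed", {
  d <- sim_mm_data(1, n = 120, n_ind = 30, n_pop = 8)
  f1 <- phylo_mmm(y ~ sex * cov, d, random = c("individual_id", "population"),
                  chain = chain_spec(3000, 500, 5, seed = 11))
  f2 <- phylo_mmm(y ~ sex * cov, d, random = c("individual_id", "population"),
                  chain = chain_spec(3000, 500, 5, seed = 11))
  expect_identical(f1$Sol, f2$Sol)
  expect_identical(f1$VCV, f2$VCV)
  expect_identical(f1$dic, f2$dic)
})

test_that("aliased fixed-effect columns are dropped with a warning", {
  d <- sim_mm_data(2, n = 100, n_ind = 25, n_pop = 5)
  d$cov2 <- d$cov
  expect_warning(
    fit <- phylo_mmm(y ~ cov + cov2, d, chain = chain_spec(1500, 300, 3)),
    "aliased")
  expect_false("cov2" %in% colnames(fit$Sol))
})

test_that("pMCMC follows the tail-mass convention", {
  set.seed(5)
  expect_gt(pmcmc(rnorm(1000)), 0.8)
  expect_equal(pmcmc(abs(rnorm(1000)) + 0.001), 1 / 1000)
  expect_equal(pmcmc(c(rep(1, 975), rep(-1, 25))), 0.05)
  expect_warning(p0 <- pmcmc(rep(0, 200)), "exactly 0")
  expect_equal(p0, 1)
  expect_error(pmcmc(rnorm(50)), ">= 100")
})

test_that("diagnostics read autocorrelation and ESS correctly", {
  set.seed(6)
  N <- 4000
  iid <- rnorm(N)
  ar1 <- as.numeric(stats::arima.sim(list(ar = 0.9), N))
  M <- cbind(iid = iid, ar1 = ar1, konst = rep(1, N))
  d <- diagnostics(M)
  expect_lt(abs(d$autocorr[d$parameter == "iid"]), 0.05)
  expect_gt(d$ess[d$parameter == "iid"], 0.85 * N)
  expect_lte(d$ess[d$parameter == "iid"], N)
  expect_equal(d$autocorr[d$parameter == "ar1"], 0.9, tolerance = 0.05)
  expect_true(d$flagged[d$parameter == "ar1"])
  expect_lte(d$ess[d$parameter == "ar1"], N)
  expect_true(d$flagged[d$parameter == "konst"])
  expect_true(is.na(d$autocorr[d$parameter == "konst"]))
})

test_that("residual variance tracks the data as priors vanish", {
  set.seed(7)
  n <- 2000
  d <- data.frame(x = rnorm(n))
  d$y <- 0.5 + d$x + rnorm(n, 0, 1.3)
  fit <- phylo_mmm(y ~ x, d, chain = chain_spec(6000, 1000, 5, seed = 3))
  s2_res <- stats::var(residuals(stats::lm(y ~ x, d)))
  expect_equal(mean(fit$VCV[, "units"]), s2_res, tolerance = 0.05 * s2_res)
})

test_that("DIC is deterministic, parsimonious, and rewards real signal", {
  # identical model/seed: identical DIC
  d <- sim_mm_data(8, n = 100, n_ind = 25, n_pop = 5)
  ch <- chain_spec(1500, 300, 3, seed = 4)
  expect_identical(phylo_mmm(y ~ cov, d, chain = ch)$dic,
                   phylo_mmm(y ~ cov, d, chain = ch)$dic)

  # data generated under the smaller model: DIC(small) <= DIC(large) + 2
  set.seed(9)
  hits <- 0
  for (r in 1:50) {
    dd <- data.frame(x = rnorm(80), z = rnorm(80))
    dd$y <- 1 + dd$x + rnorm(80)
    ch <- chain_spec(1500, 300, 3, seed = 100 + r)
    small <- phylo_mmm(y ~ x, dd, chain = ch)$dic
    large <- phylo_mmm(y ~ x + z, dd, chain = ch)$dic
    if (small <= large + 2) hits <- hits + 1
  }
  expect_gte(hits, 40)

  # a 3-sigma covariate drops DIC by more than 10
  set.seed(10)
  drops <- vapply(1:20, function(r) {
    dd <- data.frame(x = rnorm(80))
    dd$y <- 1 + 3 * dd$x + rnorm(80)
    ch <- chain_spec(1500, 300, 3, seed = 200 + r)
    phylo_mmm(y ~ 1, dd, chain = ch)$dic - phylo_mmm(y ~ x, dd, chain = ch)$dic
  }, numeric(1))
  expect_gte(mean(drops > 10), 0.95)
})

test_that("a phylogenetic random effect recovers its variance", {
  tr <- simulate_tree(30, seed = 20)
  C <- phylo_vcv(tr)
  L <- t(chol(C))
  covered <- 0
  n_rep <- 40
  for (r in 1:n_rep) {
    set.seed(300 + r)
    u <- as.numeric(L %*% rnorm(30))      # species effects, sigma2 = 1
    d <- data.frame(species = rep(tr$tip.label, each = 3))
    d$y <- u[match(d$species, tr$tip.label)] + rnorm(nrow(d), 0, 0.5)
    fit <- phylo_mmm(y ~ 1, d, random = "species", tree = tr,
                     chain = chain_spec(4000, 800, 4, seed = 300 + r))
    ci <- stats::quantile(fit$VCV[, "species"], c(0.025, 0.975))
    if (ci[1] <= 1 && 1 <= ci[2]) covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.85)
})

test_that("all-subsets DIC ranking respects marginality and finds signal", {
  # single candidate: two models
  d <- sim_mm_data(30, n = 80, n_ind = 20, n_pop = 5)
  tab <- dredge_by_dic("y", "cov", d, chain = chain_spec(1500, 300, 3))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$delta_dic[1], 0)

  # interaction never enters without its mains
  tab2 <- dredge_by_dic("y", c("cov", "cov:sex"), d, base_terms = "sex",
                        chain = chain_spec(1500, 300, 3))
  with_int <- grepl("cov:sex", tab2$model)
  expect_true(all(grepl("cov \\+|\\+ cov|~cov|~ cov", tab2$model[with_int])))

  # guard against combinatorial explosion
  expect_error(dredge_by_dic("y", sprintf("c%02d", 1:13), d), "12")

  # planted covariate among decoys is selected most of the time
  set.seed(31)
  found <- 0
  for (r in 1:20) {
    dd <- data.frame(x = rnorm(60), d1 = rnorm(60), d2 = rnorm(60),
                     d3 = rnorm(60), d4 = rnorm(60))
    dd$y <- 1 + 1.2 * dd$x + rnorm(60)
    tb <- dredge_by_dic("y", c("x", "d1", "d2", "d3", "d4"), dd,
                        chain = chain_spec(1200, 300, 3, seed = 400 + r))
    if (grepl("\\bx\\b", attr(tb, "best"))) found <- found + 1
  }
  expect_gte(found, 16)
})

test_that("an all-missing covariate enters as a null column", {
  d <- sim_mm_data(32, n = 100, n_ind = 25, n_pop = 5)
  d$gone <- NA_real_
  tab <- dredge_by_dic("y", "gone", d, chain = chain_spec(2000, 400, 4))
  expect_equal(nrow(tab), 2)
  fit <- phylo_mmm(y ~ gone,
                   within(d, gone <- as.numeric(scale_impute(cbind(gone)))),
                   chain = chain_spec(3000, 500, 5))
  ci <- stats::quantile(fit$Sol[, "gone"], c(0.025, 0.975))
  expect_true(ci[1] < 0 && ci[2] > 0)
})
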