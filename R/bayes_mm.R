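# Bayesian phylogenetic mixed models: Gaussian response, fixed effects,
# nested random intercepts, optional phylogenetically structured species
# effect, inverse-chi-square variance priors with non-central parameter
# expansion. The sampler itself lives in src/gibbs_mm.cpp.

#' Variance priors for the mixed model
#'
#' The residual (R-structure) prior is scaled-inverse-chi-square with
#' parameters `V`, `nu`; each random component (G-structure) additionally
#' carries a normal prior on a multiplicative working parameter
#' (`alpha.mu`, `alpha.V`) — non-central parameter expansion, which keeps
#' the effective variance prior weakly informative and improves mixing for
#' components with few levels. Defaults: residual V = 1, nu = 0.002;
#' random V = 1, nu = 1, alpha.mu = 0, alpha.V = 25^2.
#'
#' @param residual list(V, nu).
#' @param random list(V, nu, alpha.mu, alpha.V), recycled over components.
#' @param beta_V fixed-effect prior variance (vague by default).
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(residual = list(V = 1, nu = 0.002),
                       random = list(V = 1, nu = 1, alpha.mu = 0,
                                     alpha.V = 25^2),
                       beta_V = 1e8) {
  stopifnot(residual$V > 0, random$V > 0, random$alpha.V > 0, beta_V > 0)
  structure(list(residual = residual, random = random, beta_V = beta_V),
            class = "prior_spec")
}

#' MCMC chain settings
#'
#' @param n_iter total iterations.
#' @param burn_in discarded initial iterations.
#' @param thin keep every `thin`-th post-burn-in draw; at least 1,000 stored
#'   samples are recommended.
#' @param seed RNG seed; chains are bit-reproducible given it.
#' @return list of class `chain_spec`.
#' @export
chain_spec <- function(n_iter = 20000, burn_in = 2000, thin = 10, seed = 1) {
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1)
  n_stored <- (n_iter - burn_in) %/% thin
  if (n_stored < 100)
    warning("fewer than 100 stored samples", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 n_stored = as.integer(n_stored)),
            class = "chain_spec")
}

#' Chain presets
#'
#' `"sex_differences"` (1,750,000 / 300 / 15), `"elaboration"`
#' (300,000 / 300 / 30), `"dimorphism"` (500,000 / 500 / 30) are the
#' full-scale settings for the three analysis families; `"test"`
#' (20,000 / 2,000 / 10) is the reduced preset used by the test suite and
#' desk-scale runs.
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @export
chain_preset <- function(name = c("test", "sex_differences", "elaboration",
                                  "dimorphism"), seed = 1) {
  name <- match.arg(name)
  switch(name,
         sex_differences = chain_spec(1750000, 300, 15, seed),
         elaboration = chain_spec(300000, 300, 30, seed),
         dimorphism = chain_spec(500000, 500, 30, seed),
         test = chain_spec(20000, 2000, 10, seed))
}

# build a grouping factor from a random-term string ("a" or "a:b", the
# latter read as b nested in a, labelled by the interaction)
random_factor <- function(term, data) {
  vars <- strsplit(term, ":", fixed = TRUE)[[1]]
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("random grouping variable(s) not in data: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(vars) == 1) factor(data[[vars]])
  else interaction(lapply(vars, function(v) data[[v]]), drop = TRUE,
                   sep = ":")
}

#' Fit a Bayesian (phylogenetic) linear mixed model
#'
#' Gaussian-response mixed model fitted by a blocked Gibbs sampler: fixed
#' and random effects are drawn jointly from their multivariate normal full
#' conditional, each variance component from its scaled-inverse-chi-square
#' full conditional with a parameter-expansion working parameter, and the
#' residual variance last. A random term named in `phylo_term` (typically
#' `"species"`) is given the Brownian covariance of `tree` instead of an
#' identity structure, which is how the model controls for phylogeny.
#' Aliasing between species fixed effects and the phylogenetic random
#' effect is permitted (the prior regularises it); aliased fixed-effect
#' *columns* are dropped with a warning.
#'
#' @param formula fixed-effects formula, e.g. `y ~ sex * species`.
#' @param data data frame; rows with missing model variables are dropped.
#' @param random character vector of random-intercept terms, e.g.
#'   `c("individual_id", "species:population")`.
#' @param tree optional `phylo` whose tips cover the levels of `phylo_term`.
#' @param phylo_term which random term carries the tree covariance.
#' @param prior [prior_spec()].
#' @param chain [chain_spec()] or a [chain_preset()] name.
#' @return object of class `phylo_mmm` with posterior samples (`Sol` fixed
#'   effects, `VCV` variance components), summaries, `dic`, and the usual
#'   `print`/`summary`/`coef`/`fitted`/`residuals`/`plot` methods.
#' @export
phylo_mmm <- function(formula, data, random = character(), tree = NULL,
                      phylo_term = "species", prior = prior_spec(),
                      chain = chain_spec()) {
  if (is.character(chain)) chain <- chain_preset(chain)
  data <- as.data.frame(data)
  fvars <- all.vars(formula)
  rvars <- unique(unlist(strsplit(random, ":", fixed = TRUE)))
  use <- stats::complete.cases(data[, intersect(c(fvars, rvars), names(data)),
                                    drop = FALSE])
  n_dropped <- sum(!use)
  data <- data[use, , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!is.numeric(y) || any(!is.finite(y)))
    stop("response must be finite numeric", call. = FALSE)
  X <- stats::model.matrix(attr(mf, "terms"), mf)

  # drop aliased columns so the design is full rank; all-zero columns (e.g.
  # a fully mean-imputed covariate) are kept — their posterior is the proper
  # vague prior, centred on zero
  zero_col <- colnames(X)[apply(X, 2, function(v) all(v == 0))]
  nz <- setdiff(colnames(X), zero_col)
  qrX <- qr(X[, nz, drop = FALSE])
  if (qrX$rank < length(nz)) {
    drop_cols <- nz[qrX$pivot[(qrX$rank + 1):length(nz)]]
    warning("dropping aliased fixed-effect column(s): ",
            paste(drop_cols, collapse = ", "), call. = FALSE)
    X <- X[, setdiff(colnames(X), drop_cols), drop = FALSE]
  }

  K <- length(random)
  Zs <- list(); Ainv <- vector("list", max(K, 0)); qk <- integer(K)
  rlevels <- list()
  for (k in seq_len(K)) {
    f <- random_factor(random[k], data)
    Zk <- stats::model.matrix(~ 0 + f)
    colnames(Zk) <- levels(f)
    if (!is.null(tree) && random[k] == phylo_term) {
      C <- phylo_vcv(tree)
      miss <- setdiff(levels(f), rownames(C))
      if (length(miss))
        stop("species missing from tree: ", paste(miss, collapse = ", "),
             call. = FALSE)
      # model all tips (levels absent from the data just follow the prior)
      Zfull <- matrix(0, nrow(Zk), nrow(C),
                      dimnames = list(NULL, rownames(C)))
      Zfull[, levels(f)] <- Zk
      Zk <- Zfull
      Ainv[[k]] <- solve(C)
    }
    Zs[[k]] <- Zk
    qk[k] <- ncol(Zk)
    rlevels[[k]] <- colnames(Zk)
  }
  Z <- if (K > 0) do.call(cbind, Zs) else matrix(0, nrow(X), 0)

  set.seed(chain$seed)
  res <- gibbs_mm_cpp(
    y = y, X = X, Z = Z, qk = qk,
    Ainv_list = if (K > 0) Ainv else list(),
    Vk = rep_len(prior$random$V, K), nuk = rep_len(prior$random$nu, K),
    alpha_mu = rep_len(prior$random$alpha.mu, K),
    alpha_V = rep_len(prior$random$alpha.V, K),
    px = rep_len(1L, K),
    resid_V = prior$residual$V, resid_nu = prior$residual$nu,
    beta_prior_var = prior$beta_V,
    niter = chain$n_iter, burnin = chain$burn_in, thin = chain$thin)

  Sol <- res$Sol; colnames(Sol) <- colnames(X)
  VCV <- res$VCV; colnames(VCV) <- c(random, "units")
  dbar <- mean(res$deviance)
  s2hat <- mean(VCV[, "units"])
  dhat <- length(y) * log(2 * pi * s2hat) +
    sum((y - res$eta_mean)^2) / s2hat
  structure(list(Sol = Sol, VCV = VCV, dic = 2 * dbar - dhat,
                 deviance = res$deviance, eta_mean = res$eta_mean, y = y,
                 formula = formula, random = random,
                 phylo = !is.null(tree) && phylo_term %in% random,
                 prior = prior, chain = chain, n = length(y),
                 n_dropped = n_dropped, call = match.call()),
            class = "phylo_mmm")
}

#' Bayesian p-value of a posterior sample
#'
#' Twice the smaller posterior tail mass across zero, floored at half a
#' sample and capped at 1: `p = min(1, 2 * max(0.5/N, min(#>0, #<0)/N))`.
#'
#' @param samples numeric posterior vector (>= 100 draws).
#' @return p in (0, 1].
#' @export
pmcmc <- function(samples) {
  N <- length(samples)
  if (N < 100) stop("need >= 100 stored samples", call. = FALSE)
  if (all(samples == 0)) {
    warning("all samples exactly 0", call. = FALSE)
    return(1)
  }
  min(1, 2 * max(0.5 / N, min(sum(samples > 0), sum(samples < 0)) / N))
}

# effective sample size by Geyer's initial positive sequence estimator
ess_ips <- function(x) {
  N <- length(x)
  if (stats::sd(x) == 0 || !is.finite(stats::sd(x))) return(NA_real_)
  rho <- drop(stats::acf(x, lag.max = min(N - 1, 2000), plot = FALSE,
                         demean = TRUE)$acf)
  tau <- 0
  m <- 0
  while (2 * m + 1 < length(rho)) {
    g <- rho[2 * m + 1] + rho[2 * m + 2]
    if (g <= 0) break
    tau <- tau + 2 * g
    m <- m + 1
  }
  tau <- max(tau - 1, 1e-8)       # tau = -rho0 + 2*sum(Gamma_m), rho0 = 1
  min(N, N / tau)
}

#' Chain diagnostics: autocorrelation and effective sample size
#'
#' Lag-`lag` autocorrelation of each stored parameter chain plus the
#' initial-positive-sequence effective sample size (always <= the number of
#' stored samples). Parameters with |autocorrelation| >= 0.1 are flagged;
#' constant chains have undefined autocorrelation and are flagged too.
#'
#' @param chain `phylo_mmm` fit or a matrix of stored samples.
#' @param lag autocorrelation lag; default 1.
#' @return data frame (parameter, autocorr, ess, flagged).
#' @export
diagnostics <- function(chain, lag = 1) {
  M <- if (inherits(chain, "phylo_mmm")) cbind(chain$Sol, chain$VCV)
       else as.matrix(chain)
  out <- do.call(rbind, lapply(seq_len(ncol(M)), function(j) {
    x <- M[, j]
    if (stats::sd(x) == 0 || !is.finite(stats::sd(x))) {
      return(data.frame(parameter = colnames(M)[j], autocorr = NA_real_,
                        ess = NA_real_, flagged = TRUE))
    }
    ac <- drop(stats::acf(x, lag.max = lag, plot = FALSE)$acf)[lag + 1]
    data.frame(parameter = colnames(M)[j], autocorr = ac,
               ess = ess_ips(x), flagged = abs(ac) >= 0.1)
  }))
  rownames(out) <- NULL
  out
}

#' Deviance information criterion of a fit
#'
#' `DIC = 2 * mean(D(theta)) - D(mean theta)` with the deviance conditional
#' on the sampled fixed and random effects (the lowest-level focus).
#'
#' @param fit `phylo_mmm`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "phylo_mmm"))
  fit$dic
}

#' @export
summary.phylo_mmm <- function(object, ...) {
  summ <- function(M, with_p) {
    do.call(rbind, lapply(seq_len(ncol(M)), function(j) {
      s <- M[, j]
      data.frame(parameter = colnames(M)[j],
                 post_mean = mean(s),
                 l95 = unname(stats::quantile(s, 0.025)),
                 u95 = unname(stats::quantile(s, 0.975)),
                 ess = ess_ips(s),
                 pMCMC = if (with_p) pmcmc(s) else NA_real_)
    }))
  }
  out <- list(solutions = summ(object$Sol, TRUE),
              variances = summ(object$VCV, FALSE),
              dic = object$dic, chain = object$chain, n = object$n)
  class(out) <- "summary.phylo_mmm"
  out
}

#' @export
print.summary.phylo_mmm <- function(x, digits = 4, ...) {
  cat(sprintf("Bayesian mixed model (n = %d, %d stored samples), DIC = %.2f\n",
              x$n, x$chain$n_stored, x$dic))
  cat("\nFixed effects:\n")
  print(format(x$solutions, digits = digits), row.names = FALSE)
  cat("\nVariance components:\n")
  print(format(x$variances[, 1:5], digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
print.phylo_mmm <- function(x, ...) {
  cat("phylo_mmm fit: ", deparse(x$formula), "\n", sep = "")
  if (length(x$random))
    cat("random: ", paste(x$random, collapse = " + "),
        if (x$phylo) " (phylogenetic covariance on species)", "\n", sep = "")
  cat(sprintf("n = %d, DIC = %.2f\n", x$n, x$dic))
  invisible(x)
}

#' @export
coef.phylo_mmm <- function(object, ...) colMeans(object$Sol)

#' @export
fitted.phylo_mmm <- function(object, ...) object$eta_mean

#' @export
residuals.phylo_mmm <- function(object, ...) object$y - object$eta_mean

#' @export
plot.phylo_mmm <- function(x, parameter = colnames(x$Sol)[1], ...) {
  s <- if (parameter %in% colnames(x$Sol)) x$Sol[, parameter]
       else x$VCV[, parameter]
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(s, type = "l", xlab = "stored iteration", ylab = parameter,
                 main = "trace")
  graphics::plot(stats::density(s), main = "posterior", xlab = parameter)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' All-subsets model ranking by DIC
#'
#' Enumerates every subset of the candidate fixed-effect terms that respects
#' marginality (an interaction enters only when its main effects are
#' present), fits each with a shared chain spec, and ranks by DIC. Candidate
#' covariates are standardised and their missing values set to 0 (the
#' scaled mean) first, so every model sees the same rows. The selected model
#' is the one with fewest parameters among those within 2 DIC of the
#' minimum.
#'
#' @param response response column name.
#' @param candidates candidate fixed-effect terms (main effects and `a:b`
#'   interactions); at most 12 unless `force = TRUE`.
#' @param data data frame.
#' @param base_terms fixed-effect terms present in every model
#'   (besides the intercept), e.g. `"sex"`.
#' @param random,tree,phylo_term,prior,chain as in [phylo_mmm()].
#' @param force override the 12-term combinatorial guard.
#' @return data frame (model, n_params, dic, delta_dic) sorted by DIC;
#'   attribute `best` holds the selected model's formula string.
#' @export
dredge_by_dic <- function(response, candidates, data,
                          base_terms = character(), random = character(),
                          tree = NULL, phylo_term = "species",
                          prior = prior_spec(), chain = chain_spec(),
                          force = FALSE) {
  if (length(candidates) > 12 && !force)
    stop("more than 12 candidate terms; set force = TRUE to override",
         call. = FALSE)
  data <- as.data.frame(data)
  mains <- unique(unlist(strsplit(c(candidates, base_terms), ":", fixed = TRUE)))
  num <- mains[vapply(mains, function(v) is.numeric(data[[v]]), logical(1))]
  if (length(num))
    data[num] <- as.data.frame(scale_impute(data[, num, drop = FALSE]))

  n_cand <- length(candidates)
  subsets <- lapply(0:(2^n_cand - 1), function(m) {
    candidates[bitwAnd(m, 2^(seq_len(n_cand) - 1)) > 0]
  })
  ok <- vapply(subsets, function(s) {
    ints <- s[grepl(":", s, fixed = TRUE)]
    all(unlist(strsplit(ints, ":", fixed = TRUE)) %in%
          c(unlist(strsplit(s[!s %in% ints], ":")), base_terms,
            unlist(strsplit(base_terms, ":", fixed = TRUE))))
  }, logical(1))
  subsets <- subsets[ok]

  rows <- lapply(seq_along(subsets), function(i) {
    terms <- c(base_terms, subsets[[i]])
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    fml <- stats::as.formula(paste(response, "~", rhs))
    fit <- phylo_mmm(fml, data, random = random, tree = tree,
                     phylo_term = phylo_term, prior = prior,
                     chain = chain_spec(chain$n_iter, chain$burn_in,
                                        chain$thin,
                                        child_seed(chain$seed, i)))
    data.frame(model = paste(deparse(fml), collapse = ""),
               n_params = ncol(fit$Sol), dic = fit$dic)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$dic), , drop = FALSE]
  out$delta_dic <- out$dic - out$dic[1]
  near <- out[out$delta_dic < 2, , drop = FALSE]
  attr(out, "best") <- near$model[which.min(near$n_params)]
  rownames(out) <- NULL
  out
}
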