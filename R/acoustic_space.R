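# Random-forest acoustic spaces: supervised sex classification with
# out-of-bag error, Breiman-style unsupervised proximity (synthetic
# independent-marginal contrast class, OOB co-occupancy), and the two MDS
# bridges (principal coordinates and Kruskal's non-metric MDS) that turn a
# proximity matrix into low-dimensional song/element coordinates.

#' Random-forest settings
#'
#' Defaults follow the full-scale analysis settings (10,000 trees, minimal
#' node size 1, Gini split rule): `mtry` is 3 for song-level spaces and 5
#' for element-level spaces. Tests and desk-scale runs use fewer trees;
#' forest-derived quantities are compared with tolerances, never
#' bit-for-bit.
#'
#' @param n_trees number of trees (>= 1).
#' @param min_node_size minimal terminal node size.
#' @param mtry variables sampled at each split.
#' @param mode `"supervised"` or `"unsupervised"`.
#' @param seed integer seed; forests are deterministic given it.
#' @param permutation_importance also compute permutation importance
#'   (impurity importance is always reported)?
#' @return list of class `rf_params`.
#' @export
rf_params <- function(n_trees = 10000, min_node_size = 1, mtry = 3,
                      mode = c("supervised", "unsupervised"), seed = 1,
                      permutation_importance = FALSE) {
  mode <- match.arg(mode)
  stopifnot(n_trees >= 1, min_node_size >= 1, mtry >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 min_node_size = as.integer(min_node_size),
                 split_rule = "gini", mtry = as.integer(mtry), mode = mode,
                 seed = as.integer(seed),
                 permutation_importance = permutation_importance),
            class = "rf_params")
}

#' Supervised random-forest sex classification with out-of-bag error
#'
#' Fits a classification forest of songs (or elements) on sex labels and
#' reports the out-of-bag error — each sample is predicted only by trees
#' that did not train on it — as the measure of how separable male and
#' female songs are, plus per-sex correct-classification proportions and
#' impurity (mean decrease in Gini) variable importance.
#'
#' @param X numeric feature matrix/data frame, no missing values.
#' @param y sex labels (two classes, each with >= 2 samples).
#' @param params [rf_params()].
#' @return `sex_classification_report`: list with `oob_total_error`,
#'   `per_class_correct`, `importance`, `confusion`, `n`, `params`.
#' @export
fit_supervised_rf <- function(X, y, params = rf_params()) {
  X <- as.data.frame(X)
  y <- factor(as.character(y))
  if (nlevels(y) != 2) stop("need exactly two classes", call. = FALSE)
  if (any(table(y) < 2)) stop("each class needs >= 2 samples", call. = FALSE)
  if (anyNA(X)) stop("missing feature values", call. = FALSE)
  mtry <- min(params$mtry, ncol(X))
  set.seed(params$seed)
  rf <- randomForest::randomForest(
    x = X, y = y, ntree = params$n_trees, mtry = mtry,
    nodesize = params$min_node_size,
    importance = params$permutation_importance)
  conf <- rf$confusion
  per_class <- 1 - conf[, "class.error"]
  imp <- rf$importance[, "MeanDecreaseGini"]
  structure(list(oob_total_error = unname(rf$err.rate[params$n_trees, "OOB"]),
                 per_class_correct = per_class,
                 importance = sort(imp, decreasing = TRUE),
                 permutation_importance =
                   if (params$permutation_importance)
                     rf$importance[, "MeanDecreaseAccuracy"] else NULL,
                 confusion = conf[, seq_len(nlevels(y)), drop = FALSE],
                 n = table(y), params = params),
            class = "sex_classification_report")
}

#' @export
print.sex_classification_report <- function(x, ...) {
  cat(sprintf("Supervised RF (%d trees): OOB total correct %.1f%%\n",
              x$params$n_trees, 100 * (1 - x$oob_total_error)))
  for (cl in names(x$per_class_correct))
    cat(sprintf("  %s correct: %.1f%% (n = %d)\n", cl,
                100 * x$per_class_correct[cl], x$n[cl]))
  invisible(x)
}

#' Unsupervised random-forest proximity matrix
#'
#' Breiman's unsupervised scheme: a synthetic contrast class of the same
#' size is drawn by sampling each feature independently from its empirical
#' marginal, a two-class forest is grown, and the proximity between two
#' original samples is the fraction of qualifying trees in which they share
#' a terminal node; only trees where both samples are out-of-bag qualify
#' (OOB proximity). Synthetic rows never appear in the returned matrix.
#' Pairs with no qualifying tree get proximity 0 (with a warning).
#'
#' @param X numeric feature matrix (>= 10 rows, >= 2 columns).
#' @param params [rf_params()]; `mode` must be `"unsupervised"`.
#' @return `proximity_matrix`: list with `P` (symmetric, unit diagonal,
#'   entries in \[0, 1\]), `labels`, `oob_only = TRUE`.
#' @export
fit_unsupervised_rf_proximity <- function(X,
                                          params = rf_params(mode = "unsupervised")) {
  X <- as.data.frame(X)
  if (nrow(X) < 10) stop("need >= 10 samples", call. = FALSE)
  if (ncol(X) < 2)
    stop("need >= 2 features (marginal scrambling degenerates)", call. = FALSE)
  mtry <- min(params$mtry, ncol(X))
  set.seed(params$seed)
  rf <- randomForest::randomForest(
    x = X, y = NULL, ntree = params$n_trees, mtry = mtry,
    nodesize = params$min_node_size, proximity = TRUE, oob.prox = TRUE)
  P <- rf$proximity
  if (any(!is.finite(P))) {
    warning("pair(s) with no qualifying out-of-bag tree; proximity set to 0",
            call. = FALSE)
    P[!is.finite(P)] <- 0
  }
  P <- (P + t(P)) / 2
  diag(P) <- 1
  labels <- rownames(X)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(X)))
  dimnames(P) <- list(labels, labels)
  structure(list(P = P, labels = labels, oob_only = TRUE, params = params),
            class = "proximity_matrix")
}

#' Proximity to dissimilarity
#'
#' The standard bridge from a random-forest proximity matrix to MDS:
#' `D = 1 - P` (zero diagonal, symmetric).
#'
#' @param P `proximity_matrix` or a numeric proximity matrix.
#' @return dissimilarity matrix.
#' @export
proximity_to_distance <- function(P) {
  M <- if (inherits(P, "proximity_matrix")) P$P else as.matrix(P)
  D <- 1 - M
  diag(D) <- 0
  D
}

new_embedding <- function(coords, labels, method, k, eigenvalues = NULL,
                          stress = NULL) {
  structure(list(coords = coords, labels = labels, method = method, k = k,
                 eigenvalues = eigenvalues, stress = stress),
            class = "acoustic_embedding")
}

#' @export
print.acoustic_embedding <- function(x, ...) {
  cat(sprintf("Acoustic embedding (%s): %d points, %d axes\n",
              x$method, nrow(x$coords), ncol(x$coords)))
  if (!is.null(x$stress)) cat(sprintf("  stress: %.4f\n", x$stress))
  invisible(x)
}

#' @export
plot.acoustic_embedding <- function(x, col = 1, pch = 19, ...) {
  graphics::plot(x$coords[, 1], x$coords[, 2], col = col, pch = pch,
                 xlab = "D1", ylab = "D2", ...)
  invisible(x)
}

#' Classical (principal-coordinates) multidimensional scaling
#'
#' Double-centres -D^2/2 and eigendecomposes it (via [stats::cmdscale()]):
#' coordinates are eigenvectors scaled by the square root of the k largest
#' positive eigenvalues, ordered by decreasing eigenvalue. Negative
#' eigenvalues are reported in `eigenvalues` but their axes are never
#' returned; when fewer than `k` positive eigenvalues exist the available
#' axes are returned with a warning (an all-zero D yields all-zero
#' coordinates).
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @param k number of axes (< n).
#' @return `acoustic_embedding` with `eigenvalues` (full spectrum).
#' @export
classical_mds <- function(D, k = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(k >= 1, k < n, isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
  res <- suppressWarnings(stats::cmdscale(D, k = k, eig = TRUE))
  eig <- res$eig
  pos_tol <- 1e-12 * max(abs(eig), 1)
  npos <- sum(eig > pos_tol)
  if (npos >= k) {
    coords <- res$points[, seq_len(k), drop = FALSE]
  } else if (npos > 0) {
    warning(sprintf("only %d of %d requested axes have positive eigenvalues",
                    npos, k), call. = FALSE)
    coords <- res$points[, seq_len(npos), drop = FALSE]
  } else {
    warning("no positive eigenvalues; returning all-zero coordinates",
            call. = FALSE)
    coords <- matrix(0, n, k)
  }
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  rownames(coords) <- labels
  new_embedding(coords, labels, "classical_mds", ncol(coords),
                eigenvalues = eig)
}

#' Kruskal's non-metric multidimensional scaling
#'
#' Stress-1 minimisation with monotone regression via [MASS::isoMDS()],
#' initialised from the classical MDS solution plus `n_starts - 1` jittered
#' restarts (best stress kept). Stress is reported as a fraction in
#' \[0, 1\]. Zero off-diagonal dissimilarities (duplicate points) are
#' nudged to a tiny positive value below the smallest positive
#' dissimilarity, which preserves all ranks (primary tie handling);
#' an input where all points coincide is an error.
#'
#' @param D symmetric dissimilarity matrix, zero diagonal.
#' @param k embedding dimension; default 2.
#' @param n_starts restarts (first start is the classical solution).
#' @param seed seed for restart jitter.
#' @param maxit,tol optimiser controls.
#' @return `acoustic_embedding` with `stress`.
#' @export
kruskal_nmds <- function(D, k = 2, n_starts = 1, seed = 1,
                         maxit = 500, tol = 1e-6) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(k >= 1, k < n)
  off <- D[upper.tri(D)]
  if (all(off <= 0)) stop("all points identical: NMDS undefined", call. = FALSE)
  if (any(off <= 0)) {
    eps <- min(off[off > 0]) * 1e-6
    D[D <= 0] <- eps
    diag(D) <- 0
  }
  init <- suppressWarnings(classical_mds(D, k))$coords
  if (ncol(init) < k)
    init <- cbind(init, matrix(0, n, k - ncol(init)))
  # isoMDS needs a full-rank starting configuration
  set.seed(child_seed(seed, 0))
  csd <- apply(init, 2, stats::sd)
  jit_scale <- max(csd, 1e-8)
  if (any(csd < 1e-10))
    init <- init + matrix(stats::rnorm(n * k, 0, 1e-4 * jit_scale), n, k)
  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    start <- init
    if (s > 1) {
      set.seed(child_seed(seed, s))
      start <- init + matrix(stats::rnorm(n * k, 0, 0.1 * jit_scale), n, k)
    }
    fit <- MASS::isoMDS(stats::as.dist(D), y = start, k = k,
                        maxit = maxit, trace = FALSE, tol = tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  coords <- best$points
  rownames(coords) <- labels
  new_embedding(coords, labels, "kruskal_nmds", k,
                stress = best$stress / 100)
}
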