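# Song elaboration axes: PCA on the correlation matrix of the five
# elaboration variables (song duration, element number, element rate,
# frequency range, element diversity). The 5%/95% frequency parameters are
# excluded here: a higher or lower frequency is not by itself more
# elaborate. Songs are pooled across species and sexes so male and female
# scores live on the same axes; species and sex are modelled downstream.

elaboration_variables <- function() {
  c("song_duration", "element_number", "element_rate", "freq_range",
    "element_diversity")
}

#' Principal component analysis of song elaboration variables
#'
#' Standardises the five elaboration variables and eigendecomposes their
#' correlation matrix. Components are ordered by decreasing eigenvalue
#' (eigenvalues sum to 5 — the trace of a 5-variable correlation matrix).
#' Eigenvector signs are arbitrary, so a fixed convention is applied: within
#' each component the loading with the largest absolute value is made
#' positive. The first three components are retained for downstream
#' modelling.
#'
#' @param song_table `song_table` with >= 6 songs; the five variables must
#'   be finite with non-zero variance (element diversity filled in).
#' @return `song_pca`: list with `loadings` (5 x 5), `eigenvalues`,
#'   `center`, `scale`, `variable_names`, `n_components_kept = 3`.
#' @export
fit_pca <- function(song_table) {
  vars <- elaboration_variables()
  miss <- setdiff(vars, names(song_table))
  if (length(miss))
    stop("song table lacks: ", paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(as.data.frame(song_table)[, vars])
  if (nrow(X) < 6) stop("need >= 6 songs", call. = FALSE)
  if (any(!is.finite(X)))
    stop("non-finite elaboration variable values (is element_diversity filled?)",
         call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance variable: ", paste(vars[sds == 0], collapse = ", "),
         call. = FALSE)
  ctr <- colMeans(X)
  e <- eigen(stats::cor(X), symmetric = TRUE)
  L <- e$vectors
  # sign convention: dominant loading of each component positive
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(vars, paste0("PC", seq_along(vars)))
  structure(list(loadings = L, eigenvalues = e$values, center = ctr,
                 scale = sds, variable_names = vars, n_components_kept = 3L),
            class = "song_pca")
}

#' @export
print.song_pca <- function(x, ...) {
  cat("PCA of elaboration variables (correlation matrix)\n")
  cat("Eigenvalues:", paste(round(x$eigenvalues, 3), collapse = ", "), "\n")
  cat("Loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' @export
summary.song_pca <- function(object, ...) {
  ev <- object$eigenvalues
  data.frame(component = colnames(object$loadings),
             sd = sqrt(ev), prop_variance = ev / sum(ev),
             cum_variance = cumsum(ev) / sum(ev))
}

#' Scores on the first three elaboration components
#'
#' @param model `song_pca` fitted on the same variable set.
#' @param song_table song table; all five variables must be present and
#'   finite for every song.
#' @return n x 3 matrix of PC1-PC3 scores.
#' @export
pc_scores <- function(model, song_table) {
  stopifnot(inherits(model, "song_pca"))
  X <- as.matrix(as.data.frame(song_table)[, model$variable_names])
  if (any(!is.finite(X)))
    stop("song(s) with missing elaboration variables", call. = FALSE)
  Z <- sweep(sweep(X, 2, model$center, "-"), 2, model$scale, "/")
  S <- Z %*% model$loadings[, seq_len(model$n_components_kept), drop = FALSE]
  rownames(S) <- song_table$song_id
  S
}
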