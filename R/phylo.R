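# Phylogenetic comparative pieces: the Brownian-motion covariance implied by
# a tree, and Blomberg's K for continuous tip traits.

#' Brownian-motion phylogenetic covariance of a tree
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j;
#' `C[i, i]` is the root-to-tip depth. This is the trait covariance (up to a
#' rate) implied by Brownian evolution along the tree, and the structure a
#' phylogenetic random effect uses.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @return symmetric positive semi-definite matrix, tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  # a star tree (single basal polytomy) is fine; a genuinely unrooted
  # topology is not
  if (!ape::is.rooted(tree) && tree$Nnode > 1)
    stop("tree must be rooted (root it first)", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  ape::vcv.phylo(tree)
}

#' Blomberg's K for a continuous trait
#'
#' The ratio of the observed mean squared error of tip values around the
#' phylogenetic mean to the MSE under the tree's Brownian covariance,
#' standardised by its Brownian expectation, so K = 1 when trait similarity
#' tracks shared ancestry exactly as Brownian motion predicts, K < 1 when
#' close relatives are less similar than expected, K > 1 when they are more
#' similar. With phylogenetic mean `a = (1'C^-1 1)^-1 1'C^-1 y`:
#' `MSE0 = (y-a)'(y-a)/(n-1)`, `MSE = (y-a)'C^-1(y-a)/(n-1)`, and
#' `K = (MSE0/MSE) / ((tr(C) - n/(1'C^-1 1))/(n-1))`.
#'
#' @param tree rooted `phylo` (>= 4 tips).
#' @param tip_values named numeric, one value per tip label.
#' @return K (non-negative scalar).
#' @export
blomberg_k <- function(tree, tip_values) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 4) stop("need >= 4 species", call. = FALSE)
  if (is.null(names(tip_values)) || !all(tree$tip.label %in% names(tip_values)))
    stop("tip_values must be named and cover every tip", call. = FALSE)
  y <- as.numeric(tip_values[tree$tip.label])
  if (any(!is.finite(y))) stop("non-finite tip values", call. = FALSE)
  C <- phylo_vcv(tree)
  Ci <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance (duplicated zero-length tips?); ",
         "consider jittering zero branches by 1e-8", call. = FALSE))
  one <- rep(1, n)
  a <- drop((one %*% Ci %*% y) / (one %*% Ci %*% one))
  r <- y - a
  mse0 <- sum(r^2) / (n - 1)
  mse <- drop(r %*% Ci %*% r) / (n - 1)
  expected <- (sum(diag(C)) - n / drop(one %*% Ci %*% one)) / (n - 1)
  (mse0 / mse) / expected
}

#' Collapse songs to one trait value per species
#'
#' Species-level tip statistics for phylogenetic signal: the mean (or
#' median) over all songs of a species, pooling its populations.
#'
#' @param song_table song table.
#' @param variable column name.
#' @param fun `"mean"` (default) or `"median"`.
#' @return named numeric, species -> value.
#' @export
species_trait_values <- function(song_table, variable, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  f <- if (fun == "mean") mean else stats::median
  v <- tapply(as.data.frame(song_table)[[variable]], song_table$species, f)
  stats::setNames(as.numeric(v), names(v))
}

#' Phylogenetic signal for each song-level parameter
#'
#' @param song_table song table with element diversity filled.
#' @param tree species tree covering the table's species (>= 4).
#' @param variables parameters to assess; default all seven.
#' @return data frame (variable, K, n_species).
#' @export
phylosig_table <- function(song_table, tree, variables = song_parameters()) {
  sp <- unique(song_table$species)
  if (length(sp) < 4) stop("need >= 4 species", call. = FALSE)
  sub <- ape::keep.tip(tree, intersect(tree$tip.label, sp))
  miss <- setdiff(sp, tree$tip.label)
  if (length(miss))
    stop("species missing from tree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  K <- vapply(variables, function(v) {
    blomberg_k(sub, species_trait_values(song_table, v))
  }, numeric(1))
  data.frame(variable = variables, K = unname(K),
             n_species = length(sub$tip.label), row.names = NULL)
}
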