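# Acoustic-area dimorphism: per-sex 95% MCPs in a 2-D acoustic space and the
# three male-female divergence metrics, with balanced subsampling to remove
# sample-size asymmetry between the sexes.

z_scale_axes <- function(pts, ref) {
  mu <- colMeans(ref)
  sdv <- apply(ref, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  sweep(sweep(pts, 2, mu, "-"), 2, sdv, "/")
}

#' Per-song element diversity from an element-level acoustic space
#'
#' Element diversity of a song is the area of the 95% minimum convex polygon
#' around that song's elements in the first two axes of an element-level
#' embedding; it measures how widely a song's elements spread among all
#' elements of all songs. Songs with fewer than three elements (or a
#' degenerate hull) get area 0 and are counted in the `n_degenerate`
#' attribute.
#'
#' @param embedding `acoustic_embedding` of elements (or a coordinate
#'   matrix); only the first two axes are used.
#' @param song_ids vector mapping each embedded element to its song.
#' @param retain MCP retention proportion; default 0.95.
#' @return named numeric vector song_id -> area, attribute `n_degenerate`.
#' @export
element_diversity_scores <- function(embedding, song_ids, retain = 0.95) {
  coords <- if (inherits(embedding, "acoustic_embedding")) embedding$coords
            else as.matrix(embedding)
  stopifnot(ncol(coords) >= 2)
  coords <- coords[, 1:2, drop = FALSE]
  if (length(song_ids) != nrow(coords))
    stop("song_ids must map every embedded element", call. = FALSE)
  sp <- split(seq_along(song_ids), song_ids)
  out <- vapply(sp, function(idx) mcp(coords[idx, , drop = FALSE], retain)$area,
                numeric(1))
  n_deg <- sum(vapply(sp, function(idx) {
    mcp(coords[idx, , drop = FALSE], retain)$degenerate
  }, logical(1)))
  attr(out, "n_degenerate") <- n_deg
  out
}

#' Per-sex acoustic areas within one population
#'
#' @param points matrix of 2-D song coordinates for one population.
#' @param sexes "male"/"female" per row; both must be present.
#' @param retain MCP retention; default 0.95.
#' @return list with `male` and `female` `mcpolygon`s.
#' @export
acoustic_area_by_sex <- function(points, sexes, retain = 0.95) {
  pts <- as.matrix(points)
  sexes <- as.character(sexes)
  if (!all(c("male", "female") %in% sexes))
    stop("both sexes must be present", call. = FALSE)
  list(male = mcp(pts[sexes == "male", , drop = FALSE], retain),
       female = mcp(pts[sexes == "female", , drop = FALSE], retain))
}

#' Three male-female acoustic dimorphism metrics
#'
#' Axes are z-transformed using the pooled scaling set (the population's
#' songs of both sexes) so centroid distances are comparable across
#' populations; area *ratios* are unaffected by this affine map. Metrics:
#' \describe{
#' \item{overlap_prop}{area of the intersection of the two sex 95% MCPs as a
#'   proportion of the population's entire acoustic area (by default the
#'   union of the two polygons, which guarantees a value in \[0, 1\];
#'   `denominator = "pooled_mcp"` instead uses the MCP of the pooled points).}
#' \item{centroid_distance}{Euclidean distance between the per-sex centroids
#'   (axis-wise means) in z-units.}
#' \item{area_size_difference}{|male area - female area| over the same
#'   denominator — dimorphism in song variability.}
#' }
#' Degenerate cases: both polygons degenerate gives (0, 0, 0) with a
#' `degenerate` attribute; one degenerate gives overlap 0 and size
#' difference 1.
#'
#' @param male_points,female_points 2-D point matrices (non-empty).
#' @param pooled scaling set; default the row-bind of the two sets.
#' @param retain MCP retention; default 0.95.
#' @param denominator `"union"` (default) or `"pooled_mcp"`.
#' @return named numeric (overlap_prop, centroid_distance,
#'   area_size_difference).
#' @export
dimorphism_metrics <- function(male_points, female_points,
                               pooled = rbind(male_points, female_points),
                               retain = 0.95,
                               denominator = c("union", "pooled_mcp")) {
  denominator <- match.arg(denominator)
  m <- as.matrix(male_points); f <- as.matrix(female_points)
  stopifnot(nrow(m) >= 1, nrow(f) >= 1, ncol(m) == 2, ncol(f) == 2)
  ref <- as.matrix(pooled)
  mz <- z_scale_axes(m, ref); fz <- z_scale_axes(f, ref)
  pm <- mcp(mz, retain); pf <- mcp(fz, retain)
  cd <- sqrt(sum((colMeans(mz) - colMeans(fz))^2))
  if (pm$degenerate && pf$degenerate) {
    out <- c(overlap_prop = 0, centroid_distance = 0, area_size_difference = 0)
    attr(out, "degenerate") <- "both"
    return(out)
  }
  if (pm$degenerate || pf$degenerate) {
    out <- c(overlap_prop = 0, centroid_distance = cd, area_size_difference = 1)
    attr(out, "degenerate") <- if (pm$degenerate) "male" else "female"
    return(out)
  }
  inter <- polygon_intersection_area(pm, pf)
  denom <- if (denominator == "union") pm$area + pf$area - inter
           else mcp(z_scale_axes(ref, ref), retain)$area
  c(overlap_prop = inter / denom,
    centroid_distance = cd,
    area_size_difference = abs(pm$area - pf$area) / denom)
}

#' Dimorphism metrics under balanced subsampling
#'
#' To remove sample-size asymmetry, the sex with more songs is subsampled
#' without replacement to the size of the rarer sex; the three metrics are
#' computed on each balanced subset and averaged over `n_iter` iterations
#' (default 100). When the sexes are already balanced every iteration uses
#' the full data and the per-iteration variance is exactly zero. Each
#' iteration draws from a child seed derived from `seed` by counter, so
#' results are reproducible bit-for-bit.
#'
#' @param male_points,female_points 2-D point matrices.
#' @param pooled scaling set for the z-transform (default both sets pooled);
#'   held fixed across iterations.
#' @param n_iter iterations; default 100.
#' @param seed master seed for the subsampling.
#' @inheritParams dimorphism_metrics
#' @return `dimorphism_result`: list with `metrics` (the three means),
#'   `per_iteration` (n_iter x 3), `n_iter`, `seed`, `n_male`, `n_female`.
#' @export
balanced_subsample_dimorphism <- function(male_points, female_points,
                                          pooled = rbind(male_points, female_points),
                                          n_iter = 100, seed = 1,
                                          retain = 0.95,
                                          denominator = c("union", "pooled_mcp")) {
  denominator <- match.arg(denominator)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  m <- as.matrix(male_points); f <- as.matrix(female_points)
  n_m <- nrow(m); n_f <- nrow(f)
  k <- min(n_m, n_f)
  per <- matrix(NA_real_, n_iter, 3,
                dimnames = list(NULL, c("overlap_prop", "centroid_distance",
                                        "area_size_difference")))
  for (i in seq_len(n_iter)) {
    set.seed(child_seed(seed, i))
    mi <- if (n_m > k) m[sample.int(n_m, k), , drop = FALSE] else m
    fi <- if (n_f > k) f[sample.int(n_f, k), , drop = FALSE] else f
    per[i, ] <- dimorphism_metrics(mi, fi, pooled, retain, denominator)
  }
  structure(list(metrics = colMeans(per), per_iteration = per,
                 n_iter = n_iter, seed = seed, n_male = n_m, n_female = n_f),
            class = "dimorphism_result")
}

#' @export
print.dimorphism_result <- function(x, ...) {
  cat(sprintf("Dimorphism over %d balanced iterations (n_m=%d, n_f=%d):\n",
              x$n_iter, x$n_male, x$n_female))
  print(round(x$metrics, 4))
  invisible(x)
}
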