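# Convex-polygon primitives behind the acoustic-area metrics. Vertices are
# stored counter-clockwise; areas come from the shoelace formula.

#' Signed/absolute polygon area (shoelace formula)
#' @param v matrix of polygon vertices (2 columns), in order.
#' @param signed return the signed area (positive when counter-clockwise)?
#' @return area in embedding units squared.
#' @export
polygon_area <- function(v, signed = FALSE) {
  v <- as.matrix(v)
  if (nrow(v) < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  i2 <- c(2:nrow(v), 1)
  a <- sum(x * y[i2] - x[i2] * y) / 2
  if (signed) a else abs(a)
}

# counter-clockwise convex hull vertices of a point set (grDevices::chull
# returns the hull clockwise; orientation is fixed by the signed area)
convex_hull <- function(pts) {
  pts <- as.matrix(pts)
  h <- grDevices::chull(pts)
  v <- pts[h, , drop = FALSE]
  if (nrow(v) >= 3 && polygon_area(v, signed = TRUE) < 0)
    v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  v
}

#' Minimum convex polygon of a point cloud
#'
#' Home-range style MCP repurposed for acoustic areas: the arithmetic
#' centroid of all points is computed, points are ranked by Euclidean
#' distance to it, the nearest `ceiling(retain * n)` are kept (distance ties
#' resolved by input order), and the convex hull of the kept points is
#' returned. Fewer than three non-collinear retained points give a degenerate
#' polygon with area 0.
#'
#' @param points matrix/data frame of 2-D points (>= 1 row).
#' @param retain proportion of points to retain, in (0, 1]; default 0.95.
#' @return an object of class `mcpolygon`: list with `vertices`
#'   (counter-clockwise), `area`, `retain`, `n_points_in`, `n_points_used`,
#'   `degenerate`.
#' @export
mcp <- function(points, retain = 0.95) {
  pts <- as.matrix(points)
  stopifnot(nrow(pts) >= 1, ncol(pts) == 2, retain > 0, retain <= 1)
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  ctr <- colMeans(pts)
  d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  n_used <- ceiling(retain * n)
  keep <- order(d)[seq_len(n_used)]         # order() is stable: ties by input order
  kept <- pts[keep, , drop = FALSE]
  v <- convex_hull(kept)
  a <- polygon_area(v)
  degen <- nrow(v) < 3 || a == 0
  structure(list(vertices = if (degen) kept[!duplicated(kept), , drop = FALSE] else v,
                 area = if (degen) 0 else a,
                 retain = retain, n_points_in = n, n_points_used = n_used,
                 degenerate = degen),
            class = "mcpolygon")
}

#' @export
print.mcpolygon <- function(x, ...) {
  cat(sprintf("MCP (retain %.2f): %d/%d points, area %.6g%s\n",
              x$retain, x$n_points_used, x$n_points_in, x$area,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Polygon vertices as Well-Known Text
#' @param x mcpolygon.
#' @export
mcp_wkt <- function(x) {
  v <- rbind(x$vertices, x$vertices[1, , drop = FALSE])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.10g %.10g", v[, 1], v[, 2]), collapse = ", "))
}

# Sutherland-Hodgman clipping of convex `subject` by convex `clip`
# (both CCW vertex matrices); returns the intersection polygon (possibly
# with < 3 vertices when the intersection is empty/degenerate).
clip_convex <- function(subject, clip) {
  out <- as.matrix(subject)
  nc <- nrow(clip)
  for (k in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[k, ]; b <- clip[(k %% nc) + 1, ]
    # inside = left of directed edge a->b (CCW polygon interior)
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    inp <- out
    out <- matrix(numeric(0), 0, 2)
    m <- nrow(inp)
    s_prev <- side(inp[m, ])
    prev <- inp[m, ]
    for (i in seq_len(m)) {
      cur <- inp[i, ]
      s_cur <- side(cur)
      if (s_cur >= 0) {
        if (s_prev < 0) {
          t <- s_prev / (s_prev - s_cur)
          out <- rbind(out, prev + t * (cur - prev))
        }
        out <- rbind(out, cur)
      } else if (s_prev >= 0) {
        t <- s_prev / (s_prev - s_cur)
        out <- rbind(out, prev + t * (cur - prev))
      }
      prev <- cur; s_prev <- s_cur
    }
  }
  out
}

#' Intersection area of two convex polygons
#' @param a,b `mcpolygon` objects or CCW vertex matrices.
#' @return area of the intersection.
#' @export
polygon_intersection_area <- function(a, b) {
  va <- if (inherits(a, "mcpolygon")) a$vertices else as.matrix(a)
  vb <- if (inherits(b, "mcpolygon")) b$vertices else as.matrix(b)
  if (nrow(va) < 3 || nrow(vb) < 3) return(0)
  polygon_area(clip_convex(va, vb))
}
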