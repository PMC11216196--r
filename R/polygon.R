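# 2D polygon helpers for footprint overlap analysis.
# Polygons are n x 2 matrices of vertices in order (not closed).

poly_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(2:nrow(p), 1L)
  0.5 * sum(x * y[j] - x[j] * y)
}

#' Polygon area (shoelace)
#'
#' @param p n x 2 vertex matrix (either winding).
#' @return Absolute area.
#' @export
poly_area <- function(p) abs(poly_signed_area(p))

# ensure counter-clockwise winding
poly_ccw <- function(p) if (poly_signed_area(p) < 0) p[nrow(p):1, , drop = FALSE] else p

#' Clip a polygon by a convex polygon (Sutherland-Hodgman)
#'
#' @param subject n x 2 vertex matrix.
#' @param clip m x 2 vertex matrix; must be convex.
#' @return The intersection polygon as a k x 2 matrix (possibly 0 rows).
#' @export
clip_polygon_convex <- function(subject, clip) {
  clip <- poly_ccw(clip)
  out <- subject
  m <- nrow(clip)
  for (e in seq_len(m)) {
    if (nrow(out) == 0L) break
    a <- clip[e, ]
    b <- clip[if (e == m) 1L else e + 1L, ]
    # signed distance to edge ab (positive = inside for CCW clip)
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    inp <- out
    out <- matrix(numeric(0), 0L, 2L)
    n <- nrow(inp)
    sides <- apply(inp, 1L, side)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      p <- inp[i, ]; q <- inp[j, ]
      pin <- sides[i] >= 0
      qin <- sides[j] >= 0
      if (pin) out <- rbind(out, p)
      if (pin != qin) {
        t <- sides[i] / (sides[i] - sides[j])
        out <- rbind(out, p + t * (q - p))
      }
    }
  }
  out
}

# convex hull of points, CCW, as a matrix
poly_convex_hull <- function(p) {
  idx <- grDevices::chull(p[, 1], p[, 2])  # clockwise
  p[rev(idx), , drop = FALSE]
}

#' Overlap fraction between two footprint polygons
#'
#' Both polygons are projected to the horizontal plane and convexified; the
#' returned fraction is `area(intersection) / area(a)` (asymmetric: relative
#' to the first polygon's own area).  Convexification slightly overestimates
#' overlap for non-convex footprints, which is conservative when testing
#' disjointness.
#'
#' @param a,b n x 2 vertex matrices (or footprints' horizontal projections).
#' @return Scalar in `[0, 1]`.
#' @export
poly_overlap_frac <- function(a, b) {
  ha <- poly_convex_hull(a)
  hb <- poly_convex_hull(b)
  inter <- clip_polygon_convex(ha, hb)
  if (nrow(inter) < 3L) return(0)
  min(1, poly_area(inter) / poly_area(ha))
}

footprint_poly2d <- function(fp) {
  if (is.null(fp$vertices_local)) return(NULL)
  fp$vertices_local[, 1:2, drop = FALSE]
}
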