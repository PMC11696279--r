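# Planar geometry primitives underlying all rugae descriptors.
#
# Coordinates are unit-agnostic (mm on casts and scans, px on calibrated
# photographs); areas carry unit^2 and the compactness index is
# dimensionless, so mixed-magnification comparisons remain meaningful.
#
# Degeneracy convention: any area below 1e-12 x (bounding-box diagonal)^2
# is snapped to exactly 0, so collinear configurations behave identically
# whatever the coordinate magnitude.

DEGENERATE_AREA_REL <- 1e-12

#' Area of a triangle from the homogeneous-coordinate determinant
#'
#' Computes the unsigned triangle area as half the absolute value of the
#' determinant of the 3 x 3 matrix whose rows are `(x_i, y_i, 1)` for the
#' three vertices. Collinear (degenerate) triangles are permitted and return
#' exactly 0.
#'
#' @param tri A 3 x 2 numeric matrix of vertex coordinates (columns x, y).
#' @return Non-negative area in squared coordinate units.
#' @examples
#' triangle_area(rbind(c(0, 0), c(1, 0), c(0, 1)))  # 0.5
#' triangle_area(rbind(c(0, 0), c(2, 2), c(4, 4)))  # 0 (collinear)
#' @export
triangle_area <- function(tri) {
  tri <- as_point_matrix(tri, "triangle vertices", n_min = 3L)
  if (nrow(tri) != 3L)
    rug_abort("a triangle has exactly 3 vertices", "rugometry_invalid_input")
  h <- cbind(tri, 1)
  a <- 0.5 * abs(det(h))
  d2 <- bbox_diag2(tri)
  if (d2 > 0 && a < DEGENERATE_AREA_REL * d2) a <- 0
  a
}

#' Perimeter of a polygon (or triangle) in the given vertex order
#'
#' Sums consecutive edge lengths including the closing edge from the last
#' vertex back to the first. The vertex order is taken as given; apply
#' [canonical_polygon()] first if a simple boundary is required.
#'
#' @param pts An n x 2 matrix of vertices, n >= 3.
#' @return Total boundary length (coordinate units).
#' @export
polygon_perimeter <- function(pts) {
  pts <- as_point_matrix(pts, "polygon vertices", n_min = 3L)
  nxt <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE])
  sum(sqrt(rowSums((nxt - pts)^2)))
}

#' Compactness index (shape factor) of a closed figure
#'
#' The dimensionless ratio `area / perimeter^2`. It is invariant under any
#' similarity transform, equals `sqrt(3)/36` (about 0.048113) for every
#' equilateral triangle, and is bounded above by `1/(4*pi)` (about 0.07958),
#' attained only in the circular limit. Zero-area figures with positive
#' perimeter score exactly 0.
#'
#' @param area Non-negative area (unit^2).
#' @param perimeter Positive boundary length (unit).
#' @return Dimensionless compactness in `[0, 1/(4*pi)]`.
#' @export
compactness_index <- function(area, perimeter) {
  if (!is.numeric(area) || !is.numeric(perimeter) ||
      length(area) != 1L || length(perimeter) != 1L ||
      !is.finite(area) || !is.finite(perimeter))
    rug_abort("area and perimeter must be single finite numbers",
              "rugometry_invalid_input")
  if (perimeter < 0)
    rug_abort("perimeter must be non-negative", "rugometry_invalid_input")
  if (perimeter == 0)
    rug_abort("compactness index undefined for zero perimeter",
              "rugometry_degenerate_geometry")
  if (area == 0) return(0)
  area / perimeter^2
}

#' Canonical vertex ordering for a landmark polygon
#'
#' Sorts vertices counter-clockwise by angle about their centroid (ties
#' broken by radius), which yields a simple, non-self-intersecting boundary
#' regardless of the digitising sequence of the landmarks. The original
#' landmark sequence is preserved separately for labelling.
#'
#' @param pts An n x 2 matrix of vertices, n >= 3.
#' @return The same vertices reordered counter-clockwise about the centroid.
#' @export
canonical_polygon <- function(pts) {
  pts <- as_point_matrix(pts, "polygon vertices", n_min = 3L)
  ctr <- colMeans(pts)
  dx <- pts[, 1L] - ctr[1L]
  dy <- pts[, 2L] - ctr[2L]
  ang <- atan2(dy, dx)
  pts[order(ang, dx^2 + dy^2), , drop = FALSE]
}

# Proper/improper intersection test for two closed segments, used only for
# the simplicity check on tiny landmark polygons (O(n^2) is fine at n = 6).
#' @noRd
segments_cross <- function(p1, p2, q1, q2, eps = 1e-12) {
  orient <- function(a, b, c) {
    (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
  }
  scale <- max(abs(c(p1, p2, q1, q2)), 1)
  tol <- eps * scale^2
  d1 <- orient(q1, q2, p1); d2 <- orient(q1, q2, p2)
  d3 <- orient(p1, p2, q1); d4 <- orient(p1, p2, q2)
  if (((d1 > tol && d2 < -tol) || (d1 < -tol && d2 > tol)) &&
      ((d3 > tol && d4 < -tol) || (d3 < -tol && d4 > tol))) return(TRUE)
  on_seg <- function(a, b, c) {
    abs(orient(a, b, c)) <= tol &&
      min(a[1L], b[1L]) - tol <= c[1L] && c[1L] <= max(a[1L], b[1L]) + tol &&
      min(a[2L], b[2L]) - tol <= c[2L] && c[2L] <= max(a[2L], b[2L]) + tol
  }
  on_seg(q1, q2, p1) || on_seg(q1, q2, p2) ||
    on_seg(p1, p2, q1) || on_seg(p1, p2, q2)
}

#' Is a polygon boundary simple (non-self-intersecting)?
#' @noRd
polygon_is_simple <- function(pts) {
  n <- nrow(pts)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      # skip adjacent edges (they legitimately share an endpoint)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_cross(pts[idx[i, 1L], ], pts[idx[i, 2L], ],
                         pts[idx[j, 1L], ], pts[idx[j, 2L], ])) return(FALSE)
    }
  }
  TRUE
}

#' Area of a landmark polygon by centroid-fan triangulation
#'
#' Applies the canonical counter-clockwise ordering (unless
#' `canonicalize = FALSE`), verifies the boundary is simple, and sums
#' [triangle_area()] over the fan of triangles (centroid, v_i, v_{i+1}).
#' With angularly sorted vertices the fan wedges are disjoint, so the sum
#' equals the enclosed area.
#'
#' @param pts An n x 2 matrix of vertices, n >= 3.
#' @param canonicalize Apply [canonical_polygon()] first (default `TRUE`).
#' @return Non-negative enclosed area (unit^2).
#' @export
polygon_area <- function(pts, canonicalize = TRUE) {
  pts <- as_point_matrix(pts, "polygon vertices", n_min = 3L)
  if (canonicalize) pts <- canonical_polygon(pts)
  if (!polygon_is_simple(pts))
    rug_abort("polygon boundary self-intersects after canonical ordering",
              "rugometry_degenerate_geometry")
  ctr <- colMeans(pts)
  n <- nrow(pts)
  a <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- a + triangle_area(rbind(ctr, pts[i, ], pts[j, ]))
  }
  d2 <- bbox_diag2(pts)
  if (d2 > 0 && a < DEGENERATE_AREA_REL * d2) a <- 0
  a
}
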