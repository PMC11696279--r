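# Exact region moments of landmark polygons and Hu's invariant moments.
#
# Moments are integrated analytically over the filled polygon via Green's
# theorem (no rasterisation), so the seven Hu invariants are exact up to
# floating point and their similarity invariance holds to ~1e-12.

#' Raw geometric moments of a polygon region, orders up to 3
#'
#' Closed-form line-integral evaluation of `M_pq = integral x^p y^q dA`
#' over the region enclosed by a simple polygon with counter-clockwise
#' vertex order. Clockwise input flips all signs.
#'
#' @param pts n x 2 vertex matrix of a simple polygon.
#' @return Named list with entries `m00`, `m10`, `m01`, `m20`, `m11`,
#'   `m02`, `m30`, `m21`, `m12`, `m03`.
#' @export
polygon_raw_moments <- function(pts) {
  pts <- as_point_matrix(pts, "polygon vertices", n_min = 3L)
  x <- pts[, 1L]; y <- pts[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  a <- x * y2 - x2 * y
  list(
    m00 = sum(a) / 2,
    m10 = sum(a * (x + x2)) / 6,
    m01 = sum(a * (y + y2)) / 6,
    m20 = sum(a * (x^2 + x * x2 + x2^2)) / 12,
    m11 = sum(a * (2 * x * y + x * y2 + x2 * y + 2 * x2 * y2)) / 24,
    m02 = sum(a * (y^2 + y * y2 + y2^2)) / 12,
    m30 = sum(a * (x^3 + x^2 * x2 + x * x2^2 + x2^3)) / 20,
    m21 = sum(a * (x^2 * (3 * y + y2) + 2 * x * x2 * (y + y2) +
                     x2^2 * (y + 3 * y2))) / 60,
    m12 = sum(a * (y^2 * (3 * x + x2) + 2 * y * y2 * (x + x2) +
                     y2^2 * (x + 3 * x2))) / 60,
    m03 = sum(a * (y^3 + y^2 * y2 + y * y2^2 + y2^3)) / 20
  )
}

#' Floor-referenced signed log-magnitude transform for Hu moments
#'
#' Raw Hu invariants span many orders of magnitude, which would make a
#' Pearson correlation across the 7-vector numerically meaningless, so a
#' signed decimal log is applied:
#' `v = sign(x) * max(0, log10(|x| / floor))`.
#' Magnitudes are compressed onto a comparable decade scale (decades above
#' the reference floor) and the sign of the invariant — which carries the
#' reflection information in the seventh moment — is preserved as the sign
#' of the result. Unlike the naive `sign(x) * log10(|x|)`, this transform
#' is a continuous odd function of `x`: an invariant lying within numerical
#' noise of zero maps to a value near zero, so its (meaningless) sign
#' cannot swing the encoded value by many decades.
#'
#' @param x Numeric vector.
#' @param floor Reference magnitude: values at or below it map to 0.
#'   The default `1e-9` is of the order of the noise floor of the small
#'   third-order invariants for landmark polygons digitised at
#'   sub-millimetre precision.
#' @return Transformed vector of the same length.
#' @export
signed_log10 <- function(x, floor = 1e-9) {
  out <- numeric(length(x))
  nz <- is.finite(x) & abs(x) > floor
  out[nz] <- sign(x[nz]) * log10(abs(x[nz]) / floor)
  out
}

#' Hu invariant moments of the filled landmark polygon
#'
#' Canonically orders the six landmarks into a simple counter-clockwise
#' polygon, integrates its central moments exactly (Green's theorem),
#' normalises them, and returns the seven Hu invariants after the
#' [signed_log10()] transform. The first six are invariant under
#' translation, rotation, scaling and reflection; the seventh changes sign
#' under reflection (and hence under a flip of the image y-axis convention,
#' which is why one consistent convention must be used across the images
#' being compared).
#'
#' @param lm A [landmark_set()] or an n x 2 coordinate matrix (n >= 3).
#' @param log_transform Apply [signed_log10()] (default `TRUE`).
#' @return Named 7-vector `mom_1` ... `mom_7`.
#' @export
moment_invariants <- function(lm, log_transform = TRUE) {
  pts <- if (inherits(lm, "landmark_set")) lm$pts else lm
  pts <- as_point_matrix(pts, "landmarks", n_min = 3L)
  cp <- canonical_polygon(pts)
  area <- polygon_area(cp, canonicalize = FALSE)  # also checks simplicity
  if (area == 0)
    rug_abort("landmark polygon is degenerate; moments undefined",
              "rugometry_degenerate_geometry")
  m <- polygon_raw_moments(cp)
  ctr <- c(m$m10 / m$m00, m$m01 / m$m00)
  mu <- polygon_raw_moments(sweep(cp, 2L, ctr))
  mu00 <- mu$m00
  eta <- function(pq, ord) pq / mu00^(1 + ord / 2)
  n20 <- eta(mu$m20, 2); n02 <- eta(mu$m02, 2); n11 <- eta(mu$m11, 2)
  n30 <- eta(mu$m30, 3); n03 <- eta(mu$m03, 3)
  n21 <- eta(mu$m21, 3); n12 <- eta(mu$m12, 3)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h <- c(h1, h2, h3, h4, h5, h6, h7)
  if (log_transform) h <- signed_log10(h)
  names(h) <- paste0("mom_", 1:7)
  h
}
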