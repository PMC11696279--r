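# Internal helpers: classed error conditions, coordinate validation, and a
# local-seed evaluator so every stochastic operation is a pure function of
# (inputs, seed) without clobbering the caller's RNG stream.

#' @noRd
rug_abort <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "rugometry_error", "error", "condition"),
    list(message = message, call = sys.call(-1L), ...)
  )
  stop(cond)
}

#' Coerce to an n x 2 coordinate matrix with finite entries
#' @noRd
as_point_matrix <- function(pts, what = "coordinates", n_min = 1L) {
  if (is.data.frame(pts)) pts <- as.matrix(pts)
  if (is.null(dim(pts))) {
    if (length(pts) == 2L) pts <- matrix(as.numeric(pts), nrow = 1L)
    else rug_abort(sprintf("%s must be an n x 2 matrix", what),
                   "rugometry_invalid_input")
  }
  pts <- unname(as.matrix(pts))
  if (ncol(pts) != 2L)
    rug_abort(sprintf("%s must have exactly 2 columns (x, y)", what),
              "rugometry_invalid_input")
  storage.mode(pts) <- "double"
  if (!all(is.finite(pts)))
    rug_abort(sprintf("%s contain non-finite values", what),
              "rugometry_invalid_input")
  if (nrow(pts) < n_min)
    rug_abort(sprintf("%s need at least %d points, got %d", what, n_min, nrow(pts)),
              "rugometry_invalid_input")
  colnames(pts) <- c("x", "y")
  pts
}

#' Evaluate code under a temporary RNG seed, restoring the caller's stream
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    rug_abort("seed must be a single finite number", "rugometry_invalid_input")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Squared bounding-box diagonal, the scale reference for degeneracy snaps
#' @noRd
bbox_diag2 <- function(pts) {
  rx <- range(pts[, 1L]); ry <- range(pts[, 2L])
  (rx[2L] - rx[1L])^2 + (ry[2L] - ry[1L])^2
}
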