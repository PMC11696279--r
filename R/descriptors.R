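# The six descriptor families computed from one six-landmark configuration:
# absolute inter-landmark distances, maximum-normalised relative distances,
# landmark-polygon perimeter, area, compactness shape factor, and Hu
# invariant moments. Absolute distances, perimeter and area carry the
# coordinate unit (scaling as k, k, k^2 under magnification k); the other
# three families are similarity-invariant, so cross-modality magnification
# differences cancel in them by construction.

LM_PAIRS <- utils::combn(6L, 2L)
LM_PAIR_NAMES <- apply(LM_PAIRS, 2L, function(p) paste0("d_", p[1L], "_", p[2L]))

#' Absolute inter-landmark distances
#'
#' Euclidean distances between all C(6,2) = 15 unordered landmark pairs, in
#' fixed lexicographic pair order (1,2), (1,3), ..., (5,6).
#'
#' @param lm A [landmark_set()] or 6 x 2 coordinate matrix.
#' @return Named 15-vector of distances (coordinate units).
#' @export
absolute_distances <- function(lm) {
  pts <- if (inherits(lm, "landmark_set")) lm$pts else lm
  pts <- as_point_matrix(pts, "landmarks", n_min = 6L)
  if (nrow(pts) != 6L)
    rug_abort("absolute_distances expects exactly 6 landmarks",
              "rugometry_invalid_input")
  d <- sqrt((pts[LM_PAIRS[1L, ], 1L] - pts[LM_PAIRS[2L, ], 1L])^2 +
              (pts[LM_PAIRS[1L, ], 2L] - pts[LM_PAIRS[2L, ], 2L])^2)
  names(d) <- LM_PAIR_NAMES
  d
}

#' Relative (maximum-normalised) inter-landmark distances
#'
#' Each absolute distance divided by the largest one, giving a scale-free
#' 15-vector with maximum entry exactly 1. This makes the family invariant
#' to photograph/cast/scan magnification differences.
#'
#' @param abs_d A 15-vector from [absolute_distances()].
#' @return Named 15-vector, dimensionless, max entry 1.
#' @export
relative_distances <- function(abs_d) {
  if (!is.numeric(abs_d) || length(abs_d) != 15L || !all(is.finite(abs_d)))
    rug_abort("abs_d must be a finite 15-vector", "rugometry_invalid_input")
  mx <- max(abs_d)
  if (mx <= 0)
    rug_abort("all distances are zero; relative distances undefined",
              "rugometry_degenerate_geometry")
  out <- abs_d / mx
  names(out) <- names(abs_d) %||% LM_PAIR_NAMES
  out
}

#' Perimeter, area and shape factor of the landmark polygon
#'
#' The six landmarks are joined into their canonical (angle-sorted, simple)
#' polygon; its perimeter, enclosed area and compactness shape factor
#' (`area / perimeter^2`) are returned.
#'
#' @param lm A [landmark_set()] or 6 x 2 coordinate matrix.
#' @return Named list with `perimeter` (unit), `area` (unit^2) and
#'   `shape_factor` (dimensionless, in `(0, 1/(4*pi)]`).
#' @export
landmark_polygon_descriptors <- function(lm) {
  pts <- if (inherits(lm, "landmark_set")) lm$pts else lm
  pts <- as_point_matrix(pts, "landmarks", n_min = 3L)
  cp <- canonical_polygon(pts)
  per <- polygon_perimeter(cp)
  ar <- polygon_area(cp, canonicalize = FALSE)
  if (ar == 0 || per == 0)
    rug_abort("landmark polygon is degenerate", "rugometry_degenerate_geometry")
  list(perimeter = per, area = ar,
       shape_factor = compactness_index(ar, per))
}

#' Compute all six descriptor families for one landmark set
#'
#' @param lm A [landmark_set()].
#' @return An object of class `descriptor_set`: a list with elements
#'   `absolute_distances` (15-vector), `relative_distances` (15-vector),
#'   `perimeter`, `area`, `shape_factor` (scalars) and `moments`
#'   (7-vector of signed-log Hu invariants), plus `subject_id` and
#'   `modality` labels.
#' @export
compute_descriptors <- function(lm) {
  if (!inherits(lm, "landmark_set"))
    rug_abort("lm must be a landmark_set", "rugometry_invalid_input")
  abs_d <- absolute_distances(lm)
  rel_d <- tryCatch(relative_distances(abs_d),
                    rugometry_degenerate_geometry = function(e)
                      rug_abort("relative distances: all landmarks coincide",
                                "rugometry_degenerate_geometry"))
  poly <- tryCatch(landmark_polygon_descriptors(lm),
                   rugometry_degenerate_geometry = function(e)
                     rug_abort(paste0("polygon descriptors: ",
                                      conditionMessage(e)),
                               "rugometry_degenerate_geometry"))
  mom <- tryCatch(moment_invariants(lm),
                  rugometry_degenerate_geometry = function(e)
                    rug_abort(paste0("moments: ", conditionMessage(e)),
                              "rugometry_degenerate_geometry"))
  structure(
    list(absolute_distances = abs_d,
         relative_distances = rel_d,
         perimeter = poly$perimeter,
         area = poly$area,
         shape_factor = poly$shape_factor,
         moments = mom,
         subject_id = lm$subject_id,
         modality = lm$modality),
    class = "descriptor_set"
  )
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("Descriptor set: subject %s, modality %s\n",
              x$subject_id, x$modality))
  cat(sprintf("  perimeter %.4g, area %.4g, shape factor %.5f\n",
              x$perimeter, x$area, x$shape_factor))
  cat("  abs distances:", paste(sprintf("%.3g", x$absolute_distances[1:5]),
                                collapse = " "), "...\n")
  cat("  moments (signed log10):",
      paste(sprintf("%.3f", x$moments), collapse = " "), "\n")
  invisible(x)
}

#' Flatten descriptor sets to a one-row-per-image data frame
#'
#' Columns are family-prefixed: `abs_d_1_2` ... `abs_d_5_6`,
#' `rel_d_1_2` ... `rel_d_5_6`, `perimeter`, `area`, `shape_factor`,
#' `mom_1` ... `mom_7`, preceded by `subject_id` and `modality`.
#'
#' @param x A `descriptor_set`.
#' @param row.names,optional,... Passed on conventionally (unused).
#' @return A one-row data frame.
#' @export
as.data.frame.descriptor_set <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  vals <- c(stats::setNames(x$absolute_distances,
                            sub("^d_", "abs_d_", names(x$absolute_distances))),
            stats::setNames(x$relative_distances,
                            sub("^d_", "rel_d_", names(x$relative_distances))),
            perimeter = x$perimeter, area = x$area,
            shape_factor = x$shape_factor,
            x$moments)
  out <- as.data.frame(as.list(vals))
  cbind(data.frame(subject_id = x$subject_id, modality = x$modality,
                   stringsAsFactors = FALSE),
        out)
}

#' Write descriptor sets to a delimited text file
#'
#' @param x A `descriptor_set` or list of them.
#' @param file Output path.
#' @param sep Field separator (default tab).
#' @return Invisibly, the written data frame.
#' @export
write_descriptors <- function(x, file, sep = "\t") {
  if (inherits(x, "descriptor_set")) x <- list(x)
  df <- do.call(rbind, lapply(x, as.data.frame))
  utils::write.table(df, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(df)
}
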