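# The six-point rugae landmarking protocol.
#
# Five reference lines, all parallel to the mid-sagittal direction, are
# anchored at the interincisal point and at the central point of the collar
# of each of the four upper incisors (FDI 1.1, 1.2, 2.1, 2.2). Their
# intersections with the first two palatal rugae give six ordered landmarks:
#   1: line through 2.1 x ruga 1     4: line through 1.2 x ruga 1
#   2: line through 2.2 x ruga 1     5: line through 1.1 x ruga 2
#   3: line through 1.1 x ruga 1     6: line through 2.2 x ruga 2

#' Incisor reference frame
#'
#' Bundles the anatomical anchors of the landmark protocol: the central
#' points of the collars of the four upper incisors (FDI notation: 1.1/1.2
#' upper right central/lateral, 2.1/2.2 upper left central/lateral), the
#' interincisal point, and the unit mid-sagittal direction along which the
#' five reference lines run.
#'
#' @param collar_11,collar_12,collar_21,collar_22 Length-2 numeric vectors,
#'   collar centre coordinates of teeth 1.1, 1.2, 2.1, 2.2.
#' @param interincisal Length-2 numeric vector, the interincisal point.
#' @param sagittal_dir Length-2 numeric vector giving the mid-sagittal
#'   direction; it is normalised to unit length.
#' @return An object of class `incisor_frame`.
#' @export
incisor_frame <- function(collar_11, collar_12, collar_21, collar_22,
                          interincisal, sagittal_dir = c(0, 1)) {
  pts <- rbind(collar_11, collar_12, collar_21, collar_22, interincisal)
  pts <- as_point_matrix(pts, "incisor frame points", n_min = 5L)
  collars <- pts[1:4, , drop = FALSE]
  if (anyDuplicated(collars) > 0L)
    rug_abort("the four collar points must be pairwise distinct",
              "rugometry_invalid_input")
  d <- as.numeric(sagittal_dir)
  if (length(d) != 2L || !all(is.finite(d)))
    rug_abort("sagittal_dir must be a finite 2-vector", "rugometry_invalid_input")
  nrm <- sqrt(sum(d^2))
  if (nrm == 0)
    rug_abort("sagittal_dir must have non-zero norm", "rugometry_invalid_input")
  structure(
    list(collar_11 = pts[1L, ], collar_12 = pts[2L, ],
         collar_21 = pts[3L, ], collar_22 = pts[4L, ],
         interincisal = pts[5L, ], sagittal_dir = d / nrm),
    class = "incisor_frame"
  )
}

#' Palatal ruga polyline
#'
#' An ordered 2D polyline tracing one palatal ruga, indexed by its position
#' counted from the incisors (1 = first, i.e. most anterior, ruga).
#'
#' @param points An n x 2 matrix of polyline vertices, n >= 2, consecutive
#'   vertices distinct.
#' @param index Positive integer, the ruga number from the incisive papilla.
#' @return An object of class `ruga_curve`.
#' @export
ruga_curve <- function(points, index = 1L) {
  points <- as_point_matrix(points, "ruga polyline", n_min = 2L)
  steps <- diff(points)
  if (any(rowSums(steps^2) == 0))
    rug_abort("consecutive ruga polyline points must be distinct",
              "rugometry_invalid_input")
  if (!is.numeric(index) || length(index) != 1L || index < 1)
    rug_abort("ruga index must be a positive integer", "rugometry_invalid_input")
  structure(list(points = points, index = as.integer(index)),
            class = "ruga_curve")
}

#' Six-landmark configuration for one palatal image
#'
#' @param pts A 6 x 2 matrix of landmark coordinates in protocol order.
#' @param modality Record type: `"photo"`, `"plaster"`, `"scan"`, or
#'   `"truth"` for generator ground truth.
#' @param subject_id Subject label.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(pts, modality, subject_id) {
  pts <- as_point_matrix(pts, "landmarks", n_min = 6L)
  if (nrow(pts) != 6L)
    rug_abort("a landmark set has exactly 6 points", "rugometry_invalid_input")
  modality <- as.character(modality)[1L]
  if (!nzchar(modality))
    rug_abort("modality must be a non-empty string", "rugometry_invalid_input")
  rownames(pts) <- paste0("lm", 1:6)
  structure(list(pts = pts, modality = modality,
                 subject_id = as.character(subject_id)[1L]),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("Rugae landmark set: subject %s, modality %s\n",
              x$subject_id, x$modality))
  print(round(x$pts, 4))
  invisible(x)
}

#' Build the five parallel reference lines of the landmark protocol
#'
#' One line through the interincisal point and one through each incisor
#' collar point, all parallel to the frame's mid-sagittal direction. Lines
#' are infinite (point + direction), mirroring full-image reference lines.
#'
#' @param frame An [incisor_frame()].
#' @return A named list of five lines (`interincisal`, `t11`, `t12`, `t21`,
#'   `t22`), each a list with elements `point`, `dir` and `label`.
#' @export
build_reference_lines <- function(frame) {
  if (!inherits(frame, "incisor_frame"))
    rug_abort("frame must be an incisor_frame", "rugometry_invalid_input")
  mk <- function(p, lab) list(point = p, dir = frame$sagittal_dir, label = lab)
  list(
    interincisal = mk(frame$interincisal, "interincisal"),
    t11 = mk(frame$collar_11, "1.1"),
    t12 = mk(frame$collar_12, "1.2"),
    t21 = mk(frame$collar_21, "2.1"),
    t22 = mk(frame$collar_22, "2.2")
  )
}

#' Intersect a reference line with a ruga polyline
#'
#' Computes all crossings of the infinite line with the polyline's segments.
#' If several segments cross (a wavy ruga can meet a line twice), the
#' anterior-most crossing is returned: the one at the smallest distance
#' along the sagittal direction from the interincisal point, since rugae are
#' read from the incisive papilla backwards.
#'
#' @param line A line from [build_reference_lines()].
#' @param ruga A [ruga_curve()].
#' @param frame The [incisor_frame()] providing the anterior reference.
#' @return The crossing point as a length-2 named numeric vector.
#' @export
intersect_line_ruga <- function(line, ruga, frame) {
  if (!inherits(ruga, "ruga_curve"))
    rug_abort("ruga must be a ruga_curve", "rugometry_invalid_input")
  p0 <- as.numeric(line$point)
  d <- as.numeric(line$dir)
  pts <- ruga$points
  n <- nrow(pts)
  hits <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(n - 1L)) {
    q1 <- pts[i, ]; q2 <- pts[i + 1L, ]
    r <- q2 - q1
    denom <- d[1L] * r[2L] - d[2L] * r[1L]
    scale <- max(abs(c(r, d)), 1e-300)
    if (abs(denom) < 1e-14 * scale^2) next  # parallel segment
    w <- p0 - q1
    s <- (d[1L] * w[2L] - d[2L] * w[1L]) / denom
    if (s >= -1e-12 && s <= 1 + 1e-12) {
      hits <- rbind(hits, q1 + pmin(pmax(s, 0), 1) * r)
    }
  }
  if (nrow(hits) == 0L)
    rug_abort(sprintf("reference line '%s' does not intersect ruga %d",
                      line$label %||% "?", ruga$index),
              "rugometry_no_intersection",
              line_label = line$label %||% NA_character_,
              ruga_index = ruga$index)
  proj <- abs(as.numeric(
    (hits - matrix(frame$interincisal, nrow(hits), 2L, byrow = TRUE)) %*%
      frame$sagittal_dir))
  hit <- hits[which.min(proj), ]
  c(x = hit[[1L]], y = hit[[2L]])
}

#' Extract the six protocol landmarks from a frame and the first two rugae
#'
#' Applies the published landmark sequence: intersections of the collar
#' lines of 2.1, 2.2, 1.1, 1.2 with the first ruga (landmarks 1-4), then
#' 1.1 and 2.2 with the second ruga (landmarks 5-6).
#'
#' @param frame An [incisor_frame()].
#' @param ruga1,ruga2 [ruga_curve()] objects with indices 1 and 2.
#' @param modality,subject_id Labels stored in the resulting set.
#' @return A [landmark_set()].
#' @export
extract_landmarks <- function(frame, ruga1, ruga2, modality, subject_id) {
  if (!inherits(ruga1, "ruga_curve") || !inherits(ruga2, "ruga_curve"))
    rug_abort("ruga1 and ruga2 must be ruga_curve objects",
              "rugometry_invalid_input")
  if (ruga1$index != 1L || ruga2$index != 2L)
    rug_abort("rugae must carry indices 1 and 2", "rugometry_invalid_input")
  lines <- build_reference_lines(frame)
  plan <- list(list(lines$t21, ruga1), list(lines$t22, ruga1),
               list(lines$t11, ruga1), list(lines$t12, ruga1),
               list(lines$t11, ruga2), list(lines$t22, ruga2))
  pts <- matrix(NA_real_, 6L, 2L)
  for (k in seq_along(plan)) {
    pts[k, ] <- tryCatch(
      intersect_line_ruga(plan[[k]][[1L]], plan[[k]][[2L]], frame),
      rugometry_no_intersection = function(e) {
        rug_abort(sprintf("landmark %d: %s", k, conditionMessage(e)),
                  "rugometry_no_intersection", landmark_index = k)
      })
  }
  landmark_set(pts, modality, subject_id)
}
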