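# Pair-wise comparison of descriptor sets: Pearson correlation and
# coefficient of determination per descriptor family, with the interpretive
# bands used in forensic rugoscopy reporting.
#
# Vector families (absolute distances, relative distances, moments) are
# correlated within an image pair. The three polygon scalars (perimeter,
# area, shape factor) cannot yield a correlation alone; within a pair they
# are pooled into a 3-vector (optionally standardised per component using
# cohort statistics), while per-family scalar coefficients are obtained at
# cohort level by correlating each scalar across subjects (see
# [compare_cohort()]).
#
# The moment family is encoded with the floor-referenced signed log of
# signed_log10(): a Hu invariant lying within numerical noise of zero maps
# to ~0, so its unstable sign cannot dominate the correlation, while the
# stable signs of larger invariants retain their discriminative power.

#' Pearson correlation between two descriptor vectors
#'
#' @param a,b Equal-length numeric vectors (length >= 3) with positive
#'   variance.
#' @return The product-moment correlation, in `[-1, 1]`.
#' @export
family_correlation <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != length(b))
    rug_abort("a and b must be numeric vectors of equal length",
              "rugometry_invalid_input")
  if (length(a) < 3L)
    rug_abort("need at least 3 paired values for a correlation",
              "rugometry_invalid_input")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    rug_abort("inputs contain non-finite values", "rugometry_invalid_input")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    rug_abort("constant vector: correlation undefined",
              "rugometry_constant_vector")
  r <- stats::cor(a, b)
  # snap floating-point residue at the boundaries so that exact identity
  # (or anti-identity) yields exactly +/-1
  if (r > 1 - 1e-12) r <- 1 else if (r < -1 + 1e-12) r <- -1
  r
}

#' Coefficient of determination from a correlation coefficient
#'
#' @param r Correlation in `[-1, 1]`.
#' @return `r^2`.
#' @export
determination <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(abs(r) > 1 + 1e-9))
    rug_abort("r must lie in [-1, 1]", "rugometry_invalid_input")
  r^2
}

#' Interpretive band for a correlation coefficient
#'
#' Bands: weak (r < 0.3), moderate (0.3 to 0.7), strong (r > 0.7). The
#' published inequalities are strict on both sides, leaving the boundary
#' values undefined; here a boundary value is assigned to the lower band
#' (0.3 is weak, 0.7 is moderate) as a deterministic tie rule.
#'
#' @param r Numeric vector of correlation coefficients.
#' @return Ordered factor with levels weak < moderate < strong.
#' @export
classify_r <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)))
    rug_abort("r must be finite", "rugometry_invalid_input")
  out <- ifelse(r <= 0.3, "weak", ifelse(r <= 0.7, "moderate", "strong"))
  factor(out, levels = c("weak", "moderate", "strong"), ordered = TRUE)
}

#' Interpretive band for a coefficient of determination
#'
#' Bands: none (R2 = 0), weak (0 to 0.2), moderate (0.2 to 0.4), strong
#' (0.4 to 0.6), very strong (0.6 to 0.8), perfect (0.8 to 1.0). Boundary
#' values are assigned to the lower band (e.g. 0.4 is moderate, 0.8 is
#' very strong), the same tie rule as [classify_r()].
#'
#' @param R2 Numeric vector in `[0, 1]`.
#' @return Ordered factor with levels
#'   none < weak < moderate < strong < very strong < perfect.
#' @export
classify_R2 <- function(R2) {
  if (!is.numeric(R2) || any(!is.finite(R2)))
    rug_abort("R2 must be finite", "rugometry_invalid_input")
  if (any(R2 < -1e-12 | R2 > 1 + 1e-9))
    rug_abort("R2 must lie in [0, 1]", "rugometry_invalid_input")
  lv <- c("none", "weak", "moderate", "strong", "very strong", "perfect")
  out <- ifelse(R2 <= 0, "none",
         ifelse(R2 <= 0.2, "weak",
         ifelse(R2 <= 0.4, "moderate",
         ifelse(R2 <= 0.6, "strong",
         ifelse(R2 <= 0.8, "very strong", "perfect")))))
  factor(out, levels = lv, ordered = TRUE)
}

#' Compare two descriptor sets family by family
#'
#' Computes Pearson r, R2 = r^2 and the interpretive bands for each
#' descriptor family of an image pair: absolute distances (15-vector),
#' relative distances (15-vector), pooled polygon scalars (3-vector of
#' perimeter, area, shape factor, optionally standardised with cohort
#' statistics), and Hu moments (7-vector of floor-referenced signed logs,
#' see [signed_log10()]). A family whose vectors are constant is reported
#' as `NA` with a note, without aborting the others.
#'
#' @param a,b `descriptor_set` objects from [compute_descriptors()].
#' @param scaling_a,scaling_b Optional lists with `center` and `scale`
#'   3-vectors (perimeter, area, shape factor order) used to standardise
#'   the pooled scalar family of each side; typically the per-modality
#'   cohort mean and standard deviation supplied by [compare_cohort()].
#' @return A data frame of class `rugae_comparison` with columns `family`,
#'   `r`, `R2`, `r_band`, `R2_band`, `note`, and attributes identifying the
#'   compared subject(s) and modalities.
#' @export
compare_images <- function(a, b, scaling_a = NULL, scaling_b = NULL) {
  if (!inherits(a, "descriptor_set") || !inherits(b, "descriptor_set"))
    rug_abort("a and b must be descriptor_set objects",
              "rugometry_invalid_input")
  scalars <- function(d, scaling) {
    v <- c(d$perimeter, d$area, d$shape_factor)
    if (!is.null(scaling)) {
      sc <- ifelse(scaling$scale > 0, scaling$scale, 1)
      v <- (v - scaling$center) / sc
    }
    v
  }
  fams <- list(
    absolute_distances = list(a$absolute_distances, b$absolute_distances),
    relative_distances = list(a$relative_distances, b$relative_distances),
    polygon_scalars = list(scalars(a, scaling_a), scalars(b, scaling_b)),
    # moments enter by log-magnitude: between records of one protocol no
    # image is a reflection of another, so the invariant signs are
    # protocol-constant where stable and pure noise where near zero
    moments = list(abs(a$moments), abs(b$moments))
  )
  rows <- lapply(names(fams), function(f) {
    va <- fams[[f]][[1L]]; vb <- fams[[f]][[2L]]
    r <- tryCatch(family_correlation(as.numeric(va), as.numeric(vb)),
                  rugometry_constant_vector = function(e) NA_real_)
    note <- if (is.na(r)) "constant vector" else ""
    data.frame(family = f, r = r,
               R2 = if (is.na(r)) NA_real_ else determination(r),
               r_band = if (is.na(r)) NA_character_
                        else as.character(classify_r(r)),
               R2_band = if (is.na(r)) NA_character_
                         else as.character(classify_R2(determination(r))),
               note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "subject_a") <- a$subject_id
  attr(out, "subject_b") <- b$subject_id
  attr(out, "modality_a") <- a$modality
  attr(out, "modality_b") <- b$modality
  class(out) <- c("rugae_comparison", "data.frame")
  out
}

#' @export
print.rugae_comparison <- function(x, ...) {
  cat(sprintf("Rugae comparison: %s/%s vs %s/%s\n",
              attr(x, "subject_a"), attr(x, "modality_a"),
              attr(x, "subject_b"), attr(x, "modality_b")))
  print.data.frame(cbind(x[, "family", drop = FALSE],
                         round(x[, c("r", "R2")], 4),
                         x[, c("r_band", "R2_band")]), row.names = FALSE)
  invisible(x)
}
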