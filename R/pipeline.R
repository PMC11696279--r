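# End-to-end agreement pipeline: superimpose each subject's records, compute
# descriptors, correlate per family within subject and across the cohort,
# and aggregate into the standard agreement table plus the between-method
# Wilcoxon-Mann-Whitney comparison.

MODALITY_PAIRS <- list(
  photo_scan = c("photo", "scan"),
  photo_plaster = c("photo", "plaster"),
  scan_plaster = c("scan", "plaster")
)

SCALAR_FAMILIES <- c("perimeter", "area", "shape_factor")

FAMILY_LABELS <- c(
  absolute_distances = "Absolute distances",
  relative_distances = "Relative distances",
  perimeter = "Perimeters",
  area = "Areas",
  shape_factor = "Shape factors",
  moments = "Moments",
  polygon_scalars = "Polygon scalars (pooled)"
)

#' Compare two landmark sets end to end
#'
#' Superimposes `b` onto `a` by least-squares similarity (optional), computes
#' both descriptor sets and returns the per-family comparison.
#'
#' @param a,b [landmark_set()] objects.
#' @param align Superimpose `b` onto `a` first (default `TRUE`).
#' @param scaling_a,scaling_b Optional pooled-scalar standardisation, see
#'   [compare_images()].
#' @return A `rugae_comparison` data frame.
#' @export
compare_pair <- function(a, b, align = TRUE,
                         scaling_a = NULL, scaling_b = NULL) {
  if (align) b <- align_similarity(b, a)$aligned
  compare_images(compute_descriptors(a), compute_descriptors(b),
                 scaling_a, scaling_b)
}

#' Per-subject and cohort-level comparison of all modality pairs
#'
#' For every subject, the plaster and scan landmark sets are superimposed
#' onto the photograph by similarity alignment (mirroring the manual
#' superimposition step of the imaging protocol), descriptors are computed,
#' and each modality pair is compared. Vector families (absolute distances,
#' relative distances, moments) and the pooled polygon scalars yield one
#' coefficient per subject per pair; the individual polygon scalars
#' (perimeter, area, shape factor) are instead correlated across subjects,
#' the only level at which a single scalar can produce a coefficient.
#'
#' @param cohort A `rugae_cohort` from [generate_cohort()], or any list of
#'   subjects each holding one [landmark_set()] per modality.
#' @param align Superimpose onto the photograph first (default `TRUE`).
#' @return List of class `cohort_comparison` with `per_subject` (long data
#'   frame: subject_id, pair, family, r, R2, bands, note), `scalar_cohort`
#'   (per pair and scalar family: across-subject r, R2, bands, n) and
#'   `scalar_values` (the underlying per-subject scalar table).
#' @export
compare_cohort <- function(cohort, align = TRUE) {
  subjects <- if (inherits(cohort, "rugae_cohort")) cohort$subjects
              else cohort
  modalities <- c("photo", "plaster", "scan")
  n <- length(subjects)
  if (n < 2L)
    rug_abort("need at least 2 subjects", "rugometry_invalid_input")
  # superimpose onto the photo record and compute descriptors
  desc <- vector("list", n)
  for (i in seq_len(n)) {
    s <- subjects[[i]]
    if (!all(modalities %in% names(s)))
      rug_abort(sprintf("subject %d lacks a full photo/plaster/scan triplet", i),
                "rugometry_missing_data")
    lms <- list(photo = s$photo)
    for (m in c("plaster", "scan"))
      lms[[m]] <- if (align) align_similarity(s[[m]], s$photo)$aligned
                  else s[[m]]
    desc[[i]] <- lapply(lms, compute_descriptors)
  }
  # cohort standardisation of the pooled scalar family, per modality
  scalar_values <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(modalities, function(m) {
      d <- desc[[i]][[m]]
      data.frame(subject_id = d$subject_id, modality = m,
                 perimeter = d$perimeter, area = d$area,
                 shape_factor = d$shape_factor, stringsAsFactors = FALSE)
    }))
  }))
  scaling <- lapply(modalities, function(m) {
    v <- scalar_values[scalar_values$modality == m, SCALAR_FAMILIES]
    list(center = as.numeric(colMeans(v)),
         scale = as.numeric(apply(v, 2L, stats::sd)))
  })
  names(scaling) <- modalities
  per_subject <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(names(MODALITY_PAIRS), function(pn) {
      mp <- MODALITY_PAIRS[[pn]]
      cmp <- compare_images(desc[[i]][[mp[1L]]], desc[[i]][[mp[2L]]],
                            scaling[[mp[1L]]], scaling[[mp[2L]]])
      cbind(data.frame(subject_id = subjects[[i]]$photo$subject_id,
                       pair = pn, stringsAsFactors = FALSE),
            as.data.frame(cmp))
    }))
  }))
  rownames(per_subject) <- NULL
  scalar_cohort <- do.call(rbind, lapply(names(MODALITY_PAIRS), function(pn) {
    mp <- MODALITY_PAIRS[[pn]]
    do.call(rbind, lapply(SCALAR_FAMILIES, function(f) {
      va <- scalar_values[scalar_values$modality == mp[1L], f]
      vb <- scalar_values[scalar_values$modality == mp[2L], f]
      r <- tryCatch(family_correlation(va, vb),
                    rugometry_error = function(e) NA_real_)
      data.frame(pair = pn, family = f, r = r,
                 R2 = if (is.na(r)) NA_real_ else determination(r),
                 r_band = if (is.na(r)) NA_character_
                          else as.character(classify_r(r)),
                 R2_band = if (is.na(r)) NA_character_
                           else as.character(classify_R2(determination(r))),
                 n = length(va), stringsAsFactors = FALSE)
    }))
  }))
  rownames(scalar_cohort) <- NULL
  structure(list(per_subject = per_subject, scalar_cohort = scalar_cohort,
                 scalar_values = scalar_values, n_subjects = n),
            class = "cohort_comparison")
}

#' Mean correlation per descriptor family and modality pair
#'
#' For the vector families (absolute distances, relative distances, moments)
#' the mean of the per-subject coefficients; for the scalar families
#' (perimeter, area, shape factor) the single across-subject coefficient.
#' This is the per-family figure of merit the agreement table summarises.
#'
#' @param comparison A `cohort_comparison` from [compare_cohort()].
#' @return Data frame with columns `family`, `pair`, `mean_r`.
#' @export
family_mean_r <- function(comparison) {
  if (!inherits(comparison, "cohort_comparison"))
    rug_abort("comparison must come from compare_cohort()",
              "rugometry_invalid_input")
  ps <- comparison$per_subject
  vec <- ps[ps$family %in% c("absolute_distances", "relative_distances",
                             "moments"), ]
  agg <- stats::aggregate(r ~ family + pair, data = vec, FUN = mean,
                          na.action = stats::na.omit)
  names(agg)[names(agg) == "r"] <- "mean_r"
  sc <- comparison$scalar_cohort[, c("family", "pair", "r")]
  names(sc)[names(sc) == "r"] <- "mean_r"
  out <- rbind(agg, sc)
  rownames(out) <- NULL
  out[order(out$pair, out$family), ]
}

#' Cohort agreement report
#'
#' Produces the agreement table (one row per family, coefficient type and
#' modality pair with mean +/- SD, range, median and IQR over subjects for
#' the per-subject families; the single across-subject coefficient for the
#' scalar families) and the Wilcoxon-Mann-Whitney comparison of the
#' photo-vs-plaster against the photo-vs-scan coefficient distributions —
#' the test of whether the two impression methods capture the rugae equally
#' well.
#'
#' @param x A `rugae_cohort` or a `cohort_comparison`.
#' @param align Passed to [compare_cohort()] when `x` is a cohort.
#' @return List of class `rugae_cohort_report` with `table1` (a
#'   [summarize_cohort()] table over subjects), `scalar_coefficients`,
#'   `wmw` (pooled-r and pooled-R2 tests plus per-family p-values) and
#'   `n_subjects`.
#' @export
cohort_report <- function(x, align = TRUE) {
  comparison <- if (inherits(x, "cohort_comparison")) x
                else compare_cohort(x, align = align)
  ps <- comparison$per_subject
  long <- rbind(
    data.frame(family = ps$family, coefficient = "r", pair = ps$pair,
               subject_id = ps$subject_id, value = ps$r,
               stringsAsFactors = FALSE),
    data.frame(family = ps$family, coefficient = "R2", pair = ps$pair,
               subject_id = ps$subject_id, value = ps$R2,
               stringsAsFactors = FALSE)
  )
  table1 <- summarize_cohort(long)
  pp <- ps[ps$pair == "photo_plaster" & is.finite(ps$r), ]
  sc <- ps[ps$pair == "photo_scan" & is.finite(ps$r), ]
  wmw_r <- wmw_test(pp$r, sc$r)
  wmw_R2 <- wmw_test(pp$R2, sc$R2)
  fam_p <- vapply(unique(ps$family), function(f) {
    wmw_test(pp$r[pp$family == f], sc$r[sc$family == f])$p_value
  }, numeric(1))
  structure(
    list(table1 = table1,
         scalar_coefficients = comparison$scalar_cohort,
         wmw = list(pooled_r = wmw_r, pooled_R2 = wmw_R2,
                    per_family_r_p = fam_p),
         n_subjects = comparison$n_subjects,
         comparison = comparison),
    class = "rugae_cohort_report"
  )
}

#' @noRd
format_cell <- function(row) {
  sprintf("%.3f ± %.3f (%.3f–%.3f) %.3f (%.3f–%.3f)",
          row$mean, row$sd, row$min, row$max, row$median, row$q1, row$q3)
}

#' @export
print.rugae_cohort_report <- function(x, ...) {
  cat(sprintf("Rugae cohort agreement report (n = %d subjects)\n",
              x$n_subjects))
  cat("Per-subject coefficients, mean ± SD (range) median (IQR):\n")
  t1 <- x$table1
  for (f in unique(t1$family)) {
    cat(sprintf("  %s:\n", FAMILY_LABELS[[f]] %||% f))
    for (co in c("r", "R2")) {
      for (pn in unique(t1$pair)) {
        row <- t1[t1$family == f & t1$coefficient == co & t1$pair == pn, ]
        if (nrow(row) == 1L)
          cat(sprintf("    %-3s %-14s %s\n", co, pn, format_cell(row)))
      }
    }
  }
  cat("Across-subject coefficients (scalar families):\n")
  sc <- x$scalar_coefficients
  for (i in seq_len(nrow(sc)))
    cat(sprintf("    %-13s %-14s r = %6.3f (%s), R2 = %6.3f (%s)\n",
                FAMILY_LABELS[[sc$family[i]]] %||% sc$family[i], sc$pair[i],
                sc$r[i], sc$r_band[i], sc$R2[i], sc$R2_band[i]))
  cat(sprintf(
    "Impression-method comparison (photo-vs-plaster against photo-vs-scan):\n    pooled r:  p = %.4f\n    pooled R2: p = %.4f\n",
    x$wmw$pooled_r$p_value, x$wmw$pooled_R2$p_value))
  invisible(x)
}
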