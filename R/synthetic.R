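# Seeded synthetic palates and modality distortions.
#
# Rugae are modelled as damped sinusoidal perturbations of transverse line
# segments: individually distinct, curved and (optionally) asymmetric, with
# controllable crossing behaviour against the reference lines. Modality
# models emulate the three records of one subject: a clinical photograph
# (mild projective warp + landmark-scale noise), a plaster cast from an
# alginate impression (isotropic shrinkage + curve smoothing + noise) and
# an intraoral scan (light smoothing + noise). All magnitudes are synthetic
# configuration values in millimetres, not fitted to any measured images.
#
# Coordinate convention: the interincisal point is the origin, +y runs
# posteriorly along the mid-sagittal direction, x runs transversely
# (patient's left at negative x).

#' Specification of one synthetic palate
#'
#' @param seed Integer seed controlling every random element of the palate.
#' @param n_rugae Number of rugae curves (>= 2).
#' @param arch_width Transverse extent of the rugae field (mm).
#' @param ruga_wave_amplitude Nominal wave amplitude of a ruga (mm).
#' @param ruga_wave_frequency Nominal wave frequency (cycles/mm).
#' @param ruga_spacing Antero-posterior spacing between successive rugae (mm).
#' @param asymmetry Left/right asymmetry weight in `[0, 1]`; 0 gives
#'   mirror-symmetric rugae.
#' @param first_ruga_offset Distance from the interincisal point to the
#'   first ruga (mm).
#' @param collar_central,collar_lateral Transverse distance from the
#'   mid-sagittal line to the central/lateral incisor collar points (mm).
#' @param arch_bow Quadratic posterior bowing coefficient of the rugae
#'   (1/mm).
#' @param tilt_weight,phase_weight Relative weights of the two asymmetric
#'   wave components: a monotone transverse tilt (consistent handedness)
#'   and an individual phase-shifted wave; both are scaled by `asymmetry`
#'   and the ruga amplitude.
#' @param n_points Number of polyline vertices per ruga (forced odd so the
#'   sampling grid is exactly mirror-symmetric).
#' @return An object of class `palate_spec`.
#' @export
palate_spec <- function(seed = 1L, n_rugae = 4L, arch_width = 34,
                        ruga_wave_amplitude = 1.6, ruga_wave_frequency = 0.10,
                        ruga_spacing = 4.6, asymmetry = 0.7,
                        first_ruga_offset = 9, collar_central = 4.3,
                        collar_lateral = 7.9, arch_bow = 0.02,
                        tilt_weight = 0.9, phase_weight = 0.55,
                        n_points = 81L) {
  lens <- c(arch_width = arch_width, ruga_wave_amplitude = ruga_wave_amplitude,
            ruga_wave_frequency = ruga_wave_frequency,
            ruga_spacing = ruga_spacing, first_ruga_offset = first_ruga_offset,
            collar_central = collar_central, collar_lateral = collar_lateral)
  if (any(!is.finite(lens)) || any(lens <= 0))
    rug_abort("all lengths and the wave frequency must be positive",
              "rugometry_invalid_input")
  if (!is.finite(asymmetry) || asymmetry < 0 || asymmetry > 1)
    rug_abort("asymmetry must lie in [0, 1]", "rugometry_invalid_input")
  if (n_rugae < 2L)
    rug_abort("need at least 2 rugae", "rugometry_invalid_input")
  if (collar_lateral <= collar_central)
    rug_abort("collar_lateral must exceed collar_central",
              "rugometry_invalid_input")
  n_points <- max(21L, as.integer(n_points))
  if (n_points %% 2L == 0L) n_points <- n_points + 1L
  structure(list(seed = as.integer(seed), n_rugae = as.integer(n_rugae),
                 arch_width = arch_width,
                 ruga_wave_amplitude = ruga_wave_amplitude,
                 ruga_wave_frequency = ruga_wave_frequency,
                 ruga_spacing = ruga_spacing, asymmetry = asymmetry,
                 first_ruga_offset = first_ruga_offset,
                 collar_central = collar_central,
                 collar_lateral = collar_lateral, arch_bow = arch_bow,
                 tilt_weight = tilt_weight, phase_weight = phase_weight,
                 n_points = n_points),
            class = "palate_spec")
}

#' Generate one synthetic palate with ground-truth landmarks
#'
#' Builds the incisor frame, `n_rugae` wavy transverse polylines ordered by
#' distance from the incisors, and the ground-truth landmark set obtained
#' by interpolating each ruga at the reference-line abscissae. Deterministic
#' given `spec$seed`. With `asymmetry = 0` the rugae are even functions of
#' the transverse coordinate, so left/right landmark pairs mirror exactly.
#'
#' @param spec A [palate_spec()].
#' @return A list of class `synthetic_palate` with elements `frame`
#'   ([incisor_frame()]), `rugae` (list of [ruga_curve()]), `truth`
#'   (ground-truth [landmark_set()], modality `"truth"`) and `spec`.
#' @export
generate_palate <- function(spec) {
  if (!inherits(spec, "palate_spec"))
    rug_abort("spec must be a palate_spec", "rugometry_invalid_input")
  half <- spec$arch_width / 2
  if (spec$collar_lateral >= 0.95 * half)
    rug_abort(sprintf(
      "collar lines (|x| = %.1f) fall outside the rugae span (half-width %.1f); widen arch_width",
      spec$collar_lateral, half), "rugometry_generation_error")
  with_seed(spec$seed, {
    npos <- (spec$n_points - 1L) %/% 2L
    xp <- seq(half / npos, half, length.out = npos)
    xs <- c(-rev(xp), 0, xp)                 # exactly mirror-symmetric grid
    env <- exp(-(xs / (0.65 * half))^2)      # damping away from the midline
    rugae <- vector("list", spec$n_rugae)
    ruga_fun <- vector("list", spec$n_rugae)
    # one wave pattern per palate (rugae run roughly parallel), with small
    # per-ruga modulation on top of it
    A0 <- spec$ruga_wave_amplitude
    f0 <- spec$ruga_wave_frequency
    phi0 <- stats::runif(1, 0, 2 * pi)
    for (k in seq_len(spec$n_rugae)) {
      base_k <- spec$first_ruga_offset + (k - 1L) * spec$ruga_spacing +
        0.02 * spec$ruga_spacing * stats::runif(1, -1, 1)
      A_k <- A0 * stats::runif(1, 0.92, 1.08)
      f_k <- f0 * stats::runif(1, 0.97, 1.03)
      phi_k <- phi0 + stats::runif(1, -0.15, 0.15)
      bow_k <- spec$arch_bow * stats::runif(1, 0.95, 1.05)
      # asymmetric part: an individual phase-shifted wave plus a transverse
      # tilt, both odd-dominated, so asymmetry = 0 leaves an even function
      ys <- base_k + bow_k * xs^2 +
        env * A_k * (cos(2 * pi * f_k * xs) +
                       spec$asymmetry *
                         (spec$phase_weight * sin(2 * pi * f_k * xs + phi_k) +
                            spec$tilt_weight * sin(pi * xs / (2 * half))))
      rugae[[k]] <- ruga_curve(cbind(xs, ys), index = k)
      ruga_fun[[k]] <- list(x = xs, y = ys)
    }
    frame <- incisor_frame(
      collar_11 = c(spec$collar_central, 1.5),
      collar_12 = c(spec$collar_lateral, 3.0),
      collar_21 = c(-spec$collar_central, 1.5),
      collar_22 = c(-spec$collar_lateral, 3.0),
      interincisal = c(0, 0), sagittal_dir = c(0, 1)
    )
    # ground truth by direct interpolation of each ruga at the line abscissae
    ruga_at <- function(k, x0)
      stats::approx(ruga_fun[[k]]$x, ruga_fun[[k]]$y, xout = x0)$y
    cc <- spec$collar_central; cl <- spec$collar_lateral
    plan <- rbind(c(-cc, 1), c(-cl, 1), c(cc, 1), c(cl, 1),
                  c(cc, 2), c(-cl, 2))
    truth_pts <- t(apply(plan, 1L, function(p) c(p[1L], ruga_at(p[2L], p[1L]))))
    truth <- landmark_set(truth_pts, "truth",
                          subject_id = sprintf("seed%d", spec$seed))
    structure(list(frame = frame, rugae = rugae, truth = truth, spec = spec),
              class = "synthetic_palate")
  })
}

#' Modality distortion model
#'
#' @param kind One of `"photo"`, `"plaster"`, `"scan"`.
#' @param landmark_noise_sd SD of iid Gaussian digitising/acquisition noise
#'   added to every frame and curve point (mm).
#' @param scale_bias Isotropic magnification factor (e.g. plaster shrinkage
#'   below 1); must be positive.
#' @param projective_jitter SD of the random projective warp coefficients
#'   (1/mm), modelling camera perspective in photographs and the
#'   dome-flattening distortion of rendering a 3D palate as a 2D image for
#'   casts and scans.
#' @param smoothing_window Moving-average window applied along each ruga
#'   polyline (mm); 0 disables smoothing.
#' @return An object of class `modality_model`.
#' @export
modality_model <- function(kind = c("photo", "plaster", "scan"),
                           landmark_noise_sd = 0.2, scale_bias = 1,
                           projective_jitter = 0, smoothing_window = 0) {
  kind <- match.arg(kind)
  if (!is.finite(landmark_noise_sd) || landmark_noise_sd < 0)
    rug_abort("landmark_noise_sd must be >= 0", "rugometry_invalid_input")
  if (!is.finite(scale_bias) || scale_bias <= 0)
    rug_abort("scale_bias must be positive", "rugometry_invalid_input")
  if (!is.finite(projective_jitter) || projective_jitter < 0 ||
      !is.finite(smoothing_window) || smoothing_window < 0)
    rug_abort("projective_jitter and smoothing_window must be >= 0",
              "rugometry_invalid_input")
  structure(list(kind = kind, landmark_noise_sd = landmark_noise_sd,
                 scale_bias = scale_bias,
                 projective_jitter = projective_jitter,
                 smoothing_window = smoothing_window),
            class = "modality_model")
}

#' Default modality models of the synthetic study
#'
#' Synthetic acquisition-fidelity settings (not fitted to measured images):
#' every record carries sub-millimetre digitising noise and a small random
#' projective warp (camera perspective for the photograph; dome-flattening
#' of the 2D projection for the cast photograph and the rendered scan); the
#' plaster cast additionally shrinks isotropically by 2%, and both
#' impression-derived records are lightly smoothed. Plaster and scan share
#' identical noise, warp and smoothing magnitudes, encoding the study
#' premise that the two impression methods are equally faithful.
#'
#' @return Named list of three [modality_model()] objects
#'   (`photo`, `plaster`, `scan`).
#' @export
default_modality_models <- function() {
  list(
    photo = modality_model("photo", landmark_noise_sd = 0.05, scale_bias = 1,
                           projective_jitter = 0.003, smoothing_window = 0),
    plaster = modality_model("plaster", landmark_noise_sd = 0.05,
                             scale_bias = 0.98, projective_jitter = 0.0025,
                             smoothing_window = 1.2),
    scan = modality_model("scan", landmark_noise_sd = 0.05, scale_bias = 1,
                          projective_jitter = 0.0025, smoothing_window = 1.2)
  )
}

#' @noRd
moving_average <- function(v, halfwin) {
  n <- length(v)
  out <- v
  for (i in seq_len(n)) {
    lo <- max(1L, i - halfwin); hi <- min(n, i + halfwin)
    out[i] <- mean(v[lo:hi])
  }
  out
}

#' Apply a modality distortion to a synthetic palate
#'
#' Deterministic given `seed`. Applies, in order: isotropic scale bias about
#' the interincisal point; a small random projective warp (if
#' `projective_jitter > 0`); moving-average smoothing of each ruga polyline
#' (if `smoothing_window > 0`); iid Gaussian noise on every frame and curve
#' point (if `landmark_noise_sd > 0`). With all parameters at their identity
#' values the palate is returned unchanged.
#'
#' @param palate A `synthetic_palate` from [generate_palate()].
#' @param model A [modality_model()].
#' @param seed Integer seed for the random elements.
#' @return A list of class `synthetic_palate` with distorted `frame` and
#'   `rugae` (`truth` is dropped: it belongs to the undistorted geometry),
#'   plus the `model` applied.
#' @export
apply_modality <- function(palate, model, seed = 1L) {
  if (!inherits(palate, "synthetic_palate"))
    rug_abort("palate must be a synthetic_palate", "rugometry_invalid_input")
  if (!inherits(model, "modality_model"))
    rug_abort("model must be a modality_model", "rugometry_invalid_input")
  with_seed(seed, {
    inter <- palate$frame$interincisal
    warp <- NULL
    if (model$projective_jitter > 0)
      warp <- stats::rnorm(2L, 0, model$projective_jitter)
    distort <- function(pts) {
      if (model$scale_bias != 1)
        pts <- sweep(sweep(pts, 2L, inter) * model$scale_bias, 2L, -inter)
      if (!is.null(warp)) {
        d <- sweep(pts, 2L, inter)
        den <- 1 + d[, 1L] * warp[1L] + d[, 2L] * warp[2L]
        pts <- sweep(d / den, 2L, -inter)
      }
      pts
    }
    frame_pts <- rbind(palate$frame$collar_11, palate$frame$collar_12,
                       palate$frame$collar_21, palate$frame$collar_22,
                       palate$frame$interincisal)
    frame_pts <- distort(frame_pts)
    if (model$landmark_noise_sd > 0)
      frame_pts <- frame_pts +
        matrix(stats::rnorm(10L, 0, model$landmark_noise_sd), 5L, 2L)
    frame <- incisor_frame(frame_pts[1L, ], frame_pts[2L, ], frame_pts[3L, ],
                           frame_pts[4L, ], frame_pts[5L, ],
                           palate$frame$sagittal_dir)
    rugae <- lapply(palate$rugae, function(rg) {
      pts <- distort(rg$points)
      if (model$smoothing_window > 0) {
        spacing <- mean(sqrt(rowSums(diff(pts)^2)))
        halfwin <- floor((model$smoothing_window / spacing) / 2)
        if (halfwin >= 1L) {
          pts[, 1L] <- moving_average(pts[, 1L], halfwin)
          pts[, 2L] <- moving_average(pts[, 2L], halfwin)
        }
      }
      if (model$landmark_noise_sd > 0)
        pts <- pts + matrix(stats::rnorm(length(pts), 0,
                                         model$landmark_noise_sd),
                            nrow(pts), 2L)
      ruga_curve(pts, rg$index)
    })
    structure(list(frame = frame, rugae = rugae, truth = NULL,
                   spec = palate$spec, model = model),
              class = "synthetic_palate")
  })
}

#' Population-level variability of synthetic palates
#'
#' Means and SDs (or ranges) from which per-subject palate parameters are
#' drawn by [generate_cohort()]. Values are millimetre-scale choices
#' representative of adult palatal anatomy (incisor widths, rugae spacing of
#' a few mm, rugae field about 30 mm wide), with modest between-subject
#' variability. `elongation_sd` controls the arch-form factor: each subject
#' draws an elongation `e` (broad-shallow arches at `e < 1`, narrow-deep at
#' `e > 1`) that multiplies the antero-posterior dimensions (ruga spacing
#' and offset) and divides the transverse ones (collar distances, arch
#' width), so overall palate size varies while the enclosed landmark area
#' stays comparatively conserved — the classic brachy- vs dolicho-uranic
#' contrast.
#'
#' @return Named list of `c(mean, sd)` pairs (a range for `asymmetry`, a
#'   single sd for `elongation_sd`).
#' @export
cohort_population <- function() {
  list(
    arch_width = c(mean = 34, sd = 0.8),
    ruga_wave_amplitude = c(mean = 1.6, sd = 0.3),
    ruga_wave_frequency = c(mean = 0.10, sd = 0.015),
    ruga_spacing = c(mean = 4.6, sd = 0.18),
    first_ruga_offset = c(mean = 9, sd = 0.6),
    collar_central = c(mean = 4.3, sd = 0.12),
    collar_lateral = c(mean = 7.9, sd = 0.15),
    arch_bow = c(mean = 0.02, sd = 0.004),
    asymmetry = c(min = 0.5, max = 0.9),
    elongation_sd = 0.12
  )
}

#' Generate a cohort of per-subject modality triplets
#'
#' Draws independent palates for `n_subjects` subjects (parameters sampled
#' from [cohort_population()]), applies each modality model, and extracts
#' the six protocol landmarks from every distorted record. The ground-truth
#' landmark set of each undistorted palate is retained.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param models Named list of [modality_model()] objects (default
#'   [default_modality_models()]).
#' @param master_seed Integer master seed; all subject and modality streams
#'   are spawned from it, so cohorts are fully reproducible.
#' @param population Population variability, see [cohort_population()].
#' @return An object of class `rugae_cohort`: list with `subjects` (each a
#'   list holding `truth` plus one [landmark_set()] per modality and the
#'   subject's `spec`), `models`, `master_seed`, `n_subjects`.
#' @export
generate_cohort <- function(n_subjects, models = default_modality_models(),
                            master_seed = 1L,
                            population = cohort_population()) {
  if (!is.numeric(n_subjects) || n_subjects < 2L)
    rug_abort("n_subjects must be at least 2", "rugometry_invalid_input")
  n_subjects <- as.integer(n_subjects)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    rug_abort("models must be a named list of modality_model objects",
              "rugometry_invalid_input")
  draw <- function(par, n) stats::rnorm(n, par[["mean"]], par[["sd"]])
  setup <- with_seed(master_seed, {
    seeds <- matrix(sample.int(.Machine$integer.max,
                               n_subjects * (1L + length(models))),
                    nrow = n_subjects)
    pop <- population
    elong <- stats::rnorm(n_subjects, 1, pop$elongation_sd %||% 0)
    elong <- pmin(pmax(elong, 0.8), 1.25)
    params <- data.frame(
      arch_width = pmax(26, draw(pop$arch_width, n_subjects)) / elong,
      ruga_wave_amplitude = pmax(0.4, draw(pop$ruga_wave_amplitude, n_subjects)),
      ruga_wave_frequency = pmax(0.045, draw(pop$ruga_wave_frequency, n_subjects)),
      ruga_spacing = pmax(1.8, draw(pop$ruga_spacing, n_subjects)) * elong,
      first_ruga_offset = pmax(6, draw(pop$first_ruga_offset, n_subjects)) * elong,
      collar_central = pmax(3.4, draw(pop$collar_central, n_subjects)) / elong,
      collar_lateral = pmax(6.4, draw(pop$collar_lateral, n_subjects)) / elong,
      arch_bow = pmax(0.005, draw(pop$arch_bow, n_subjects)),
      asymmetry = stats::runif(n_subjects, pop$asymmetry[["min"]],
                               pop$asymmetry[["max"]])
    )
    params$collar_lateral <- pmax(params$collar_lateral,
                                  params$collar_central + 2.2)
    params$arch_width <- pmax(params$arch_width, 2.4 * params$collar_lateral)
    list(seeds = seeds, params = params)
  })
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%03d", i)
    pr <- setup$params[i, ]
    res <- tryCatch({
      spec <- palate_spec(seed = setup$seeds[i, 1L],
                          arch_width = pr$arch_width,
                          ruga_wave_amplitude = pr$ruga_wave_amplitude,
                          ruga_wave_frequency = pr$ruga_wave_frequency,
                          ruga_spacing = pr$ruga_spacing,
                          asymmetry = pr$asymmetry,
                          first_ruga_offset = pr$first_ruga_offset,
                          collar_central = pr$collar_central,
                          collar_lateral = pr$collar_lateral,
                          arch_bow = pr$arch_bow)
      palate <- generate_palate(spec)
      truth <- palate$truth
      truth$subject_id <- sid
      subj <- list(truth = truth, spec = spec)
      for (m in seq_along(models)) {
        mod_name <- names(models)[m]
        dist <- apply_modality(palate, models[[mod_name]],
                               seed = setup$seeds[i, 1L + m])
        subj[[mod_name]] <- extract_landmarks(dist$frame, dist$rugae[[1L]],
                                              dist$rugae[[2L]],
                                              modality = mod_name,
                                              subject_id = sid)
      }
      subj
    }, rugometry_error = function(e) {
      rug_abort(sprintf("subject %d (%s): %s", i, sid, conditionMessage(e)),
                "rugometry_generation_error", subject = i)
    })
    subjects[[i]] <- res
  }
  structure(list(subjects = subjects, models = models,
                 master_seed = as.integer(master_seed),
                 n_subjects = n_subjects),
            class = "rugae_cohort")
}

#' @export
print.rugae_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic rugae cohort: %d subjects x %d modalities (%s), master seed %d\n",
    x$n_subjects, length(x$models), paste(names(x$models), collapse = ", "),
    x$master_seed))
  invisible(x)
}
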