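make_frame <- function(cc = 4, cl = 9, sag = c(0, 1)) {
  incisor_frame(collar_11 = c(cc, 1), collar_12 = c(cl, 2),
                collar_21 = c(-cc, 1), collar_22 = c(-cl, 2),
                interincisal = c(0, 0), sagittal_dir = sag)
}

test_that("five reference lines are parallel and anchored as specified", {
  fr <- make_frame()
  lines <- build_reference_lines(fr)
  expect_length(lines, 5L)
  xs <- sort(unname(vapply(lines, function(l) l$point[[1L]], numeric(1))))
  expect_equal(xs, c(-9, -4, 0, 4, 9))
  dirs <- t(vapply(lines, function(l) l$dir, numeric(2)))
  expect_true(all(apply(dirs, 1, function(d) isTRUE(all.equal(d, c(0, 1))))))
  expect_error(incisor_frame(c(1, 1), c(2, 2), c(3, 3), c(4, 4), c(0, 0),
                             sagittal_dir = c(0, 0)),
               class = "rugometry_invalid_input")
})

test_that("rotating the frame rotates all reference lines (equivariance)", {
  fr <- make_frame()
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  fr_rot <- incisor_frame(as.numeric(R %*% fr$collar_11),
                          as.numeric(R %*% fr$collar_12),
                          as.numeric(R %*% fr$collar_21),
                          as.numeric(R %*% fr$collar_22),
                          as.numeric(R %*% fr$interincisal),
                          as.numeric(R %*% fr$sagittal_dir))
  l0 <- build_reference_lines(fr)
  l1 <- build_reference_lines(fr_rot)
  for (nm in names(l0)) {
    expect_equal(l1[[nm]]$point, as.numeric(R %*% l0[[nm]]$point),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(l1[[nm]]$dir, as.numeric(R %*% l0[[nm]]$dir),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("line-ruga intersection returns the anterior-most crossing", {
  fr <- make_frame()
  flat <- ruga_curve(rbind(c(0, 2), c(3, 2)), 1)
  line <- list(point = c(1, 0), dir = c(0, 1), label = "t")
  expect_equal(intersect_line_ruga(line, flat, fr), c(x = 1, y = 2))
  # line entirely missing the polyline
  miss <- list(point = c(10, 0), dir = c(0, 1), label = "t")
  expect_error(intersect_line_ruga(miss, flat, fr),
               class = "rugometry_no_intersection")
  # a ruga that doubles back crosses a vertical line twice; the anterior
  # crossing (smallest |y|, since the interincisal point is at the origin
  # and the sagittal direction is +y) must be returned. Brute force over
  # all segment crossings provides the expected value.
  set.seed(12)
  for (i in 1:20) {
    y_lo <- stats::runif(1, 6, 9)
    y_hi <- y_lo + stats::runif(1, 2, 5)
    x_turn <- stats::runif(1, 3, 6)
    snake <- ruga_curve(rbind(c(-5, y_lo), c(x_turn, y_lo),
                              c(x_turn, y_hi), c(-5, y_hi)), 1)
    x0 <- stats::runif(1, -4, x_turn - 0.5)
    ln <- list(point = c(x0, 0), dir = c(0, 1), label = "t")
    # brute force: crossings of x = x0 with every segment
    hits <- c()
    segs <- snake$points
    for (k in seq_len(nrow(segs) - 1)) {
      x1 <- segs[k, 1]; x2 <- segs[k + 1, 1]
      if ((x1 - x0) * (x2 - x0) <= 0 && x1 != x2) {
        s <- (x0 - x1) / (x2 - x1)
        hits <- c(hits, segs[k, 2] + s * (segs[k + 1, 2] - segs[k, 2]))
      }
    }
    expect_gte(length(hits), 2L)
    got <- intersect_line_ruga(ln, snake, fr)
    expect_equal(got[["y"]], min(abs(hits)), tolerance = 1e-9)
  }
})

test_that("the six landmarks follow the published sequence", {
  fr <- make_frame(cc = 4, cl = 8)
  r1 <- ruga_curve(rbind(c(-12, 10), c(12, 10)), 1)
  r2 <- ruga_curve(rbind(c(-12, 14), c(12, 14)), 2)
  lm <- extract_landmarks(fr, r1, r2, "photo", "s1")
  expect_s3_class(lm, "landmark_set")
  # landmarks 1-4 on ruga 1, 5-6 on ruga 2
  expect_equal(unname(lm$pts[1:4, 2]), rep(10, 4))
  expect_equal(unname(lm$pts[5:6, 2]), rep(14, 2))
  # order: 2.1, 2.2, 1.1, 1.2 on ruga 1, then 1.1, 2.2 on ruga 2
  expect_equal(unname(lm$pts[, 1]), c(-4, -8, 4, 8, 4, -8))
  # collar lines outside the ruga span: error naming the landmark index
  short <- ruga_curve(rbind(c(-2, 10), c(2, 10)), 1)
  err <- tryCatch(extract_landmarks(fr, short, r2, "photo", "s1"),
                  rugometry_no_intersection = function(e) e)
  expect_s3_class(err, "rugometry_no_intersection")
  expect_match(conditionMessage(err), "landmark [0-9]")
})

test_that("landmark extraction is equivariant under similarity transforms", {
  pal <- generate_palate(palate_spec(seed = 33))
  lm0 <- extract_landmarks(pal$frame, pal$rugae[[1]], pal$rugae[[2]],
                           "photo", "s")
  k <- 1.7; th <- 40 * pi / 180; tr <- c(5, -3)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tp <- function(p) as.numeric(k * R %*% p + tr)
  fr2 <- incisor_frame(tp(pal$frame$collar_11), tp(pal$frame$collar_12),
                       tp(pal$frame$collar_21), tp(pal$frame$collar_22),
                       tp(pal$frame$interincisal),
                       as.numeric(R %*% pal$frame$sagittal_dir))
  rg2 <- lapply(pal$rugae, function(rg)
    ruga_curve(transform_points(rg$points, k, th, tr), rg$index))
  lm1 <- extract_landmarks(fr2, rg2[[1]], rg2[[2]], "photo", "s")
  expect_equal(lm1$pts, transform_points(lm0$pts, k, th, tr),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("similarity alignment recovers exact transforms", {
  lm <- asymmetric_landmarks()
  id <- align_similarity(lm, lm)
  expect_equal(id$scale, 1, tolerance = 1e-12)
  expect_equal(id$rotation, 0, tolerance = 1e-12)
  expect_equal(id$translation, c(0, 0), tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(id$rmsd, 1e-12)
  # moving is the original; fixed is a rotated (25 deg) scaled (x1.5) copy:
  # the fitted transform must be exactly that similarity
  th <- 25 * pi / 180
  fixed <- landmark_set(transform_points(lm$pts, 1.5, th, c(2, -7)),
                        "scan", "osub")
  fit <- align_similarity(lm, fixed)
  expect_equal(fit$scale, 1.5, tolerance = 1e-9)
  expect_equal(fit$rotation, th, tolerance = 1e-9)
  expect_lt(fit$rmsd, 1e-9)
  # degenerate: all moving points coincide
  flat <- landmark_set(matrix(1, 6, 2), "photo", "x")
  expect_error(align_similarity(flat, lm),
               class = "rugometry_degenerate_geometry")
})

test_that("alignment of noisy copies attains the grid-search optimum", {
  set.seed(44)
  for (i in 1:5) {
    lm <- asymmetric_landmarks()
    noisy <- landmark_set(
      transform_points(lm$pts, stats::runif(1, 0.7, 1.4),
                       stats::runif(1, -pi / 3, pi / 3),
                       stats::rnorm(2, 0, 4)) + matrix(stats::rnorm(12, 0, 0.4), 6, 2),
      "scan", "osub")
    fit <- align_similarity(noisy, lm)
    oracle <- grid_search_alignment_ssr(noisy, lm)
    expect_lt(abs(fit$ssr - oracle), 1e-6 + 1e-6 * oracle)
    expect_lte(fit$ssr, oracle + 1e-9)
  }
})

test_that("normalised alignment residual is symmetric in the two sets", {
  set.seed(46)
  for (i in 1:10) {
    A <- landmark_set(matrix(stats::rnorm(12, 0, 5), 6, 2), "photo", "a")
    B <- landmark_set(matrix(stats::rnorm(12, 0, 5), 6, 2), "scan", "a")
    nab <- align_similarity(A, B)$ssr / sum(scale(B$pts, scale = FALSE)^2)
    nba <- align_similarity(B, A)$ssr / sum(scale(A$pts, scale = FALSE)^2)
    expect_equal(nab, nba, tolerance = 1e-9)
  }
})
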