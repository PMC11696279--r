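unit_hexagon <- function() {
  ang <- 2 * pi * (0:5) / 6
  landmark_set(cbind(cos(ang), sin(ang)), "photo", "hex")
}

test_that("absolute distances cover all 15 pairs in lexicographic order", {
  line6 <- landmark_set(cbind(0:5, 0), "photo", "line")
  d <- absolute_distances(line6)
  expect_length(d, 15L)
  expect_equal(unname(d[["d_1_2"]]), 1)
  expect_equal(unname(d[["d_1_6"]]), 5)
  expect_equal(names(d)[1:6],
               c("d_1_2", "d_1_3", "d_1_4", "d_1_5", "d_1_6", "d_2_3"))
  # brute-force double loop oracle
  set.seed(3)
  pts <- matrix(stats::rnorm(12, 0, 8), 6, 2)
  d2 <- absolute_distances(landmark_set(pts, "photo", "r"))
  k <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    k <- k + 1
    expect_identical(unname(d2[[k]]), sqrt(sum((pts[i, ] - pts[j, ])^2)))
  }
})

test_that("relative distances are max-normalised and scale-free", {
  v <- c(3, 4, 5, rep(2, 12))
  r <- relative_distances(v)
  expect_equal(unname(r[1:3]), c(0.6, 0.8, 1.0))
  expect_equal(max(r), 1)
  expect_equal(relative_distances(v * 13.7), r, tolerance = 1e-14,
               ignore_attr = TRUE)
  set.seed(8)
  for (i in 1:10) {
    w <- stats::runif(15, 0.1, 9)
    expect_equal(unname(relative_distances(w)), w / max(w))
  }
  expect_error(relative_distances(rep(0, 15)),
               class = "rugometry_degenerate_geometry")
})

test_that("landmark polygon descriptors match the regular-hexagon closed form", {
  hex <- unit_hexagon()
  pd <- landmark_polygon_descriptors(hex)
  expect_equal(pd$perimeter, 6, tolerance = 1e-12)
  expect_equal(pd$area, 3 * sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(pd$shape_factor, (3 * sqrt(3) / 2) / 36, tolerance = 1e-12)
  expect_lt(pd$shape_factor, 1 / (4 * pi))
  # similarity invariance of the shape factor
  set.seed(9)
  for (i in 1:20) {
    lm <- asymmetric_landmarks()
    q <- landmark_set(
      transform_points(lm$pts, stats::runif(1, 0.3, 3),
                       stats::runif(1, -pi, pi), stats::rnorm(2, 0, 10)),
      "scan", "t")
    expect_lt(rel_diff(landmark_polygon_descriptors(q)$shape_factor,
                       landmark_polygon_descriptors(lm)$shape_factor), 1e-10)
  }
  # area equals the shoelace oracle on random convex configurations
  set.seed(10)
  for (i in 1:30) {
    p <- random_convex_polygon(6)
    pd2 <- landmark_polygon_descriptors(landmark_set(p, "photo", "c"))
    expect_lt(rel_diff(pd2$area, shoelace_area(p)), 1e-12)
  }
})

test_that("raw polygon moments match rectangle closed forms", {
  a <- 2; b <- 3
  rect <- rbind(c(0, 0), c(a, 0), c(a, b), c(0, b))
  m <- polygon_raw_moments(rect)
  expect_equal(m$m00, a * b, tolerance = 1e-14)
  expect_equal(m$m10, a^2 * b / 2, tolerance = 1e-14)
  expect_equal(m$m01, a * b^2 / 2, tolerance = 1e-14)
  expect_equal(m$m20, a^3 * b / 3, tolerance = 1e-14)
  expect_equal(m$m11, a^2 * b^2 / 4, tolerance = 1e-14)
  expect_equal(m$m02, a * b^3 / 3, tolerance = 1e-14)
  expect_equal(m$m30, a^4 * b / 4, tolerance = 1e-14)
  expect_equal(m$m21, a^3 * b^2 / 6, tolerance = 1e-14)
  expect_equal(m$m12, a^2 * b^3 / 6, tolerance = 1e-14)
  expect_equal(m$m03, a * b^4 / 4, tolerance = 1e-14)
})

test_that("Hu invariants of a rectangle match their closed forms", {
  a <- 2; b <- 3
  rect <- rbind(c(0, 0), c(a, 0), c(a, b), c(0, b))
  h <- moment_invariants(rect, log_transform = FALSE)
  e20 <- a / (12 * b); e02 <- b / (12 * a)
  expect_equal(unname(h[[1]]), e20 + e02, tolerance = 1e-12)
  expect_equal(unname(h[[2]]), (e20 - e02)^2, tolerance = 1e-12)
  # all third-order invariants vanish for a centrally symmetric shape
  expect_true(all(abs(h[3:7]) < 1e-15))
})

test_that("Hu moments are invariant under similarity transforms", {
  lm <- asymmetric_landmarks()
  m0 <- moment_invariants(lm)
  shifted <- landmark_set(sweep(lm$pts, 2, c(-31.7, 12.9), "-"), "photo", "t")
  expect_equal(moment_invariants(shifted), m0, tolerance = 1e-9)
  rotsc <- landmark_set(transform_points(lm$pts, 2.3, 37 * pi / 180, c(4, 4)),
                        "photo", "t")
  expect_lt(max(rel_diff(moment_invariants(rotsc), m0)), 1e-6)
})

test_that("mirroring flips only the seventh Hu invariant", {
  set.seed(14)
  for (i in 1:10) {
    p <- random_simple_polygon(6, scale = 6)
    h <- moment_invariants(p, log_transform = FALSE)
    hm <- moment_invariants(cbind(-p[, 1], p[, 2]), log_transform = FALSE)
    expect_lt(max(rel_diff(h[1:6], hm[1:6])), 1e-6)
    expect_lt(rel_diff(abs(h[[7]]), abs(hm[[7]])), 1e-6)
    if (abs(h[[7]]) > 1e-12) expect_identical(sign(h[[7]]), -sign(hm[[7]]))
    # and the same property holds through the signed-log encoding (checked
    # away from the clamp floor, where the encoding is exactly 0 anyway)
    mask <- abs(h) > 1e-8
    v <- signed_log10(h); vm <- signed_log10(hm)
    expect_equal(abs(v[mask]), abs(vm[mask]), tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("the signed-log encoding is an odd, floor-clamped transform", {
  expect_identical(signed_log10(0), 0)
  expect_identical(signed_log10(1e-12), 0)        # below the floor
  expect_equal(signed_log10(1e-6), 3)             # 3 decades above 1e-9
  expect_equal(signed_log10(-1e-6), -3)
  x <- c(-1e-3, 1e-8, -1e-10, 0.5)
  expect_equal(signed_log10(-x), -signed_log10(x))
})

test_that("compute_descriptors is consistent with the standalone families", {
  lm <- asymmetric_landmarks()
  d <- compute_descriptors(lm)
  expect_identical(d$absolute_distances, absolute_distances(lm))
  expect_identical(d$relative_distances,
                   relative_distances(absolute_distances(lm)))
  pd <- landmark_polygon_descriptors(lm)
  expect_identical(d$perimeter, pd$perimeter)
  expect_identical(d$area, pd$area)
  expect_identical(d$shape_factor, pd$shape_factor)
  expect_identical(d$moments, moment_invariants(lm))
  # deterministic: repeated calls byte-identical
  expect_identical(compute_descriptors(lm), d)
  # degenerate landmark sets are rejected with a family-naming error
  flat <- landmark_set(cbind(1:6, 1:6), "photo", "flat")
  expect_error(compute_descriptors(flat),
               class = "rugometry_degenerate_geometry")
})

test_that("descriptor families obey their scaling laws", {
  lm <- asymmetric_landmarks()
  d0 <- compute_descriptors(lm)
  set.seed(15)
  for (i in 1:10) {
    k <- stats::runif(1, 0.2, 4)
    q <- landmark_set(transform_points(lm$pts, k, stats::runif(1, -pi, pi),
                                       stats::rnorm(2, 0, 5)), "photo", "t")
    d1 <- compute_descriptors(q)
    expect_lt(max(rel_diff(d1$absolute_distances, k * d0$absolute_distances)), 1e-9)
    expect_lt(max(rel_diff(d1$relative_distances, d0$relative_distances)), 1e-9)
    expect_lt(rel_diff(d1$perimeter, k * d0$perimeter), 1e-9)
    expect_lt(rel_diff(d1$area, k^2 * d0$area), 1e-9)
    expect_lt(rel_diff(d1$shape_factor, d0$shape_factor), 1e-9)
    expect_lt(max(rel_diff(d1$moments, d0$moments)), 1e-6)
  }
})

test_that("descriptor serialisation round-trips through a flat table", {
  lm <- asymmetric_landmarks()
  df <- as.data.frame(compute_descriptors(lm))
  expect_equal(nrow(df), 1L)
  expect_true(all(c("subject_id", "modality", "abs_d_1_2", "rel_d_5_6",
                    "perimeter", "area", "shape_factor", "mom_7") %in% names(df)))
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write_descriptors(compute_descriptors(lm), f)
  back <- utils::read.delim(f)
  expect_equal(back$abs_d_1_2, df$abs_d_1_2, tolerance = 1e-12)
  expect_equal(back$mom_3, df$mom_3, tolerance = 1e-12)
})
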