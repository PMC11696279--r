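# Independent oracles used across the suite. These deliberately re-derive
# quantities by routes the package does not take (shoelace instead of
# determinant/fan, grid search instead of SVD, exhaustive permutation
# instead of rank-sum enumeration, pair counting for U).

rel_diff <- function(a, b) {
  d <- abs(a - b)
  s <- pmax(abs(a), abs(b))
  ifelse(s > 0, d / s, d)
}

# Signed shoelace area, independent of the package's determinant/fan route
shoelace_area <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  0.5 * abs(sum(x * y2 - x2 * y))
}

# Random simple polygon: angular sort of random points (star-shaped)
random_simple_polygon <- function(n, scale = 10) {
  pts <- matrix(stats::rnorm(2L * n, 0, scale), n, 2L)
  ctr <- colMeans(pts)
  pts[order(atan2(pts[, 2L] - ctr[2L], pts[, 1L] - ctr[1L])), ]
}

# Random convex polygon: points on a circle, sorted by angle
random_convex_polygon <- function(n, radius = 5) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  radius * cbind(cos(ang), sin(ang))
}

# A generic asymmetric landmark hexagon (non-degenerate Hu invariants)
asymmetric_landmarks <- function(subject = "osub", modality = "photo") {
  pts <- rbind(c(-4.1, 9.3), c(-8.2, 11.6), c(4.6, 8.8),
               c(7.7, 12.4), c(4.2, 14.9), c(-7.6, 16.2))
  landmark_set(pts, modality, subject)
}

# Zooming grid-search oracle for the least-squares similarity fit:
# translation is solved in closed form for each (rotation, scale) node.
grid_search_alignment_ssr <- function(moving, fixed, iterations = 8L) {
  X <- moving$pts; Y <- fixed$pts
  mx <- colMeans(X); my <- colMeans(Y)
  ssr_at <- function(theta, s) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
    t_vec <- my - s * as.numeric(R %*% mx)
    fit <- sweep(s * (X %*% t(R)), 2L, -t_vec)
    sum((fit - Y)^2)
  }
  th0 <- 0; ls0 <- 0
  th_span <- pi; ls_span <- 1.5
  best <- Inf
  for (it in seq_len(iterations)) {
    ths <- th0 + seq(-th_span, th_span, length.out = 17L)
    lss <- ls0 + seq(-ls_span, ls_span, length.out = 17L)
    for (th in ths) for (ls in lss) {
      v <- ssr_at(th, exp(ls))
      if (v < best) { best <- v; th0 <- th; ls0 <- ls }
    }
    th_span <- th_span * 0.3
    ls_span <- ls_span * 0.3
  }
  best
}

# Exhaustive-permutation Mann-Whitney oracle via pair counting
wmw_permutation_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); N <- length(pooled)
  u_of <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(a, b)
  combos <- utils::combn(N, n1)
  us <- apply(combos, 2L, function(idx) u_of(pooled[idx], pooled[-idx]))
  tol <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + tol), mean(us >= u_obs - tol)))
}

# Streaming (Welford) mean/sd oracle
streaming_mean_sd <- function(v) {
  m <- 0; s <- 0; k <- 0
  for (x in v) {
    k <- k + 1
    d <- x - m
    m <- m + d / k
    s <- s + d * (x - m)
  }
  c(mean = m, sd = sqrt(s / (k - 1)))
}

# Quantile by explicit linear interpolation of order statistics
interp_quantile <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# Small ready-made synthetic palate triplet for pipeline tests
demo_triplet <- function(seed = 11) {
  co <- generate_cohort(2, master_seed = seed)
  co$subjects[[1L]]
}
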