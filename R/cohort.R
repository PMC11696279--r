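# Cohort-level statistics: summary tables of comparison coefficients
# (mean +/- SD, range, median, IQR), the Wilcoxon-Mann-Whitney comparison
# of the two impression methods, and the paired-design sample-size
# calculator.

#' Summarise comparison coefficients into a cohort table
#'
#' Aggregates a long data frame of coefficients into one row per group with
#' sample mean, sample SD (n-1 denominator), range, median and quartiles
#' (type-7 linear interpolation). These are the conventions behind
#' "mean +/- SD (range) median (IQR)" agreement tables.
#'
#' @param data Data frame holding one coefficient value per row.
#' @param value Name of the numeric value column (default `"value"`).
#' @param by Character vector of grouping column names
#'   (default `c("family", "coefficient", "pair")`; only those present in
#'   `data` are used).
#' @return Data frame of class `cohort_summary` with the grouping columns
#'   plus `n`, `mean`, `sd`, `min`, `max`, `median`, `q1`, `q3`.
#' @export
summarize_cohort <- function(data, value = "value",
                             by = c("family", "coefficient", "pair")) {
  if (!is.data.frame(data) || !value %in% names(data))
    rug_abort(sprintf("data must be a data frame with a '%s' column", value),
              "rugometry_invalid_input")
  by <- intersect(by, names(data))
  if (length(by) == 0L)
    rug_abort("no grouping columns found in data", "rugometry_invalid_input")
  key <- interaction(data[by], drop = TRUE, sep = " / ", lex.order = TRUE)
  pieces <- split(data, key)
  rows <- lapply(names(pieces), function(cell) {
    v <- pieces[[cell]][[value]]
    v <- v[is.finite(v)]
    if (length(v) < 2L)
      rug_abort(sprintf("cell '%s' has %d usable values (need >= 2)",
                        cell, length(v)),
                "rugometry_missing_data", cell = cell)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    cbind(pieces[[cell]][1L, by, drop = FALSE],
          data.frame(n = length(v), mean = mean(v), sd = stats::sd(v),
                     min = min(v), max = max(v),
                     median = q[2L], q1 = q[1L], q3 = q[3L]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Wilcoxon-Mann-Whitney two-sample test
#'
#' Two-sided Mann-Whitney U test comparing two sets of coefficients. For
#' small samples (both groups below 8) the p-value is computed by exhaustive
#' enumeration of all rank assignments (ties handled by average ranks); for
#' larger samples the tie-corrected normal approximation with continuity
#' correction is used. `method` can force either branch.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 3.
#' @param method `"auto"` (default), `"exact"`, or `"normal"`.
#' @param alpha Significance level for the convenience flag (default 0.05).
#' @return List of class `wmw_test` with `U` (statistic of `group_a`),
#'   `p_value`, `significant`, `method`, and the group sizes.
#' @export
wmw_test <- function(group_a, group_b, method = c("auto", "exact", "normal"),
                     alpha = 0.05) {
  method <- match.arg(method)
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 3L || length(b) < 3L)
    rug_abort("each group needs at least 3 values", "rugometry_invalid_input")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    rug_abort("groups contain non-finite values", "rugometry_invalid_input")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L)
    rug_abort("all values tied across both groups; test is degenerate",
              "rugometry_degenerate_test")
  rk <- rank(pooled)
  W <- sum(rk[seq_len(n1)])             # rank sum of group_a
  U <- W - n1 * (n1 + 1) / 2            # Mann-Whitney U of group_a
  if (method == "auto")
    method <- if (n1 < 8L && n2 < 8L) "exact" else "normal"
  if (method == "exact") {
    if (choose(N, n1) > 5e5)
      rug_abort("exact enumeration infeasible at this sample size; use method = 'normal'",
                "rugometry_invalid_input")
    combos <- utils::combn(N, n1)
    sums <- colSums(matrix(rk[combos], nrow = n1))
    tol <- 1e-8
    p <- min(1, 2 * min(mean(sums <= W + tol), mean(sums >= W - tol)))
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(rk)
    sigma2 <- (n1 * n2 / 12) *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0)
      rug_abort("zero variance under ties; test is degenerate",
                "rugometry_degenerate_test")
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
  }
  structure(list(U = U, p_value = p, significant = p < alpha,
                 method = method, n1 = n1, n2 = n2, alpha = alpha),
            class = "wmw_test")
}

#' @export
print.wmw_test <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon-Mann-Whitney (%s): U = %g, n = %d/%d, p = %.4g (%ssignificant at %.2g)\n",
    x$method, x$U, x$n1, x$n2, x$p_value,
    if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Sample size for a paired design
#'
#' Number of subjects needed to detect a mean paired difference `delta`
#' with standard deviation `sigma` at two-sided significance `alpha` and
#' the requested power, by the normal-approximation formula for a paired
#' t-test: `n = ceil((z_{alpha/2} + z_beta)^2 * sigma^2 / delta^2)`.
#' z-quantiles are exact by default; `rounded_z = TRUE` uses the
#' conventional two-decimal values (e.g. 1.96 and 1.28) often quoted in
#' print, which can lower the result by one subject.
#'
#' @param alpha Two-sided significance level, in (0, 1).
#' @param power Desired power `1 - beta`, in (0, 1).
#' @param sigma Standard deviation of the paired differences (same unit as
#'   `delta`, e.g. mm).
#' @param delta Minimum detectable mean difference (> 0).
#' @param rounded_z Use z-quantiles rounded to two decimals.
#' @return Integer number of subjects.
#' @export
paired_sample_size <- function(alpha = 0.05, power = 0.90, sigma, delta,
                               rounded_z = FALSE) {
  for (v in list(alpha = alpha, power = power)) {
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      rug_abort("alpha and power must lie strictly between 0 and 1",
                "rugometry_invalid_input")
  }
  if (!is.numeric(sigma) || sigma <= 0 || !is.numeric(delta) || delta <= 0)
    rug_abort("sigma and delta must be positive", "rugometry_invalid_input")
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  if (rounded_z) {
    z_a <- round(z_a, 2)
    z_b <- round(z_b, 2)
  }
  as.integer(ceiling((z_a + z_b)^2 * sigma^2 / delta^2))
}
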