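#' Welch's unequal-variance t test
#'
#' @param x,y numeric samples with at least 2 values and nonzero variance.
#' @return list with `t`, `df` (Welch-Satterthwaite) and two-sided `p`.
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs >= 2 values", call. = FALSE)
  if (var(x) == 0 && var(y) == 0)
    stop("both samples are degenerate (zero variance)", call. = FALSE)
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Bonferroni correction
#'
#' `p' = min(1, m * p)` with `m` at least the number of tests.
#'
#' @param p_values numeric vector of raw p values in \[0, 1\].
#' @param m number of comparisons (default `length(p_values)`).
#' @return adjusted p values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]", call. = FALSE)
  if (m < length(p_values))
    stop("m must be >= number of tests", call. = FALSE)
  p.adjust(p_values, method = "bonferroni", n = m)
}

#' Cohen's d (pooled-SD variant)
#'
#' `d = (mean(y) - mean(x)) / s_pooled` with the classic pooled standard
#' deviation `sqrt(((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2))`.
#'
#' @param x,y numeric samples with at least 2 values.
#' @return the effect size `d`.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each sample needs >= 2 values", call. = FALSE)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 == 0) stop("zero pooled standard deviation", call. = FALSE)
  (mean(y) - mean(x)) / sqrt(sp2)
}

#' Percentile bootstrap CI for the standardized mean difference
#'
#' Resamples both groups independently with replacement and returns the
#' percentile 95% interval of [cohens_d()] over the resamples.
#'
#' @param x,y numeric samples with at least 3 values each.
#' @param n_boot number of resamples (>= 1000).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param conf confidence level (default 0.95).
#' @return list with `lo`, `hi`, the point estimate `d` and `n_boot`.
#' @export
bootstrap_ci_mean_diff <- function(x, y, n_boot = 5000L, seed, conf = 0.95) {
  if (length(x) < 3L || length(y) < 3L)
    stop("samples too small for the bootstrap (need >= 3)", call. = FALSE)
  if (n_boot < 1000L) stop("n_boot must be >= 1000", call. = FALSE)
  ds <- with_seed(seed, function() {
    vapply(seq_len(n_boot), function(i) {
      xb <- x[sample.int(length(x), replace = TRUE)]
      yb <- y[sample.int(length(y), replace = TRUE)]
      sp2 <- ((length(xb) - 1) * var(xb) + (length(yb) - 1) * var(yb)) /
        (length(xb) + length(yb) - 2)
      if (sp2 == 0) return(0) # degenerate resample: no standardized effect
      (mean(yb) - mean(xb)) / sqrt(sp2)
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  qs <- unname(quantile(ds, c(a, 1 - a), type = 7))
  list(lo = qs[1], hi = qs[2], d = cohens_d(x, y), n_boot = n_boot)
}

#' One-sample and paired t tests
#'
#' One-sample mode tests the mean of `deltas` against zero (used for
#' per-region changes in predictive power); paired mode tests the mean of
#' `deltas - y` against zero.
#'
#' @param deltas numeric sample.
#' @param mode `"one_sample"` or `"paired"`.
#' @param y second sample (paired mode only, same length as `deltas`).
#' @return list with `t` and two-sided `p`.
#' @export
t_tests <- function(deltas, mode = c("one_sample", "paired"), y = NULL) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    if (is.null(y) || length(y) != length(deltas))
      stop("paired mode needs `y` of the same length", call. = FALSE)
    deltas <- deltas - y
  }
  if (all(deltas == 0)) return(list(t = 0, p = 1))  # exactly no difference
  ht <- t.test(deltas, mu = 0)
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r` and `p` (from the t transform of r).
#' @export
pearson_r_p <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length samples with n >= 3", call. = FALSE)
  ht <- cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = unname(ht$p.value))
}

#' Mann-Whitney U statistic with midrank ties
#'
#' `U` counts the pairs `(x_i, y_j)` with `x_i > y_j`, ties counted half;
#' the normalized statistic `U / (n_x * n_y)` lies in \[0, 1\] with 0.5 for
#' indistinguishable distributions.
#'
#' @param x,y nonempty numeric samples.
#' @return list with `U` and `normalized_U`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("samples must be nonempty", call. = FALSE)
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))  # midranks
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  list(U = U, normalized_U = U / (nx * ny))
}
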