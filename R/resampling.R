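#' Two-tailed nonparametric randomization test for two independent groups
#'
#' Tests whether two groups of observations (e.g. per-cluster open
#' probabilities under two agonists) differ, by permuting group labels. The
#' test statistic is the absolute difference of group means (difference of
#' medians available). When the number of distinct label assignments is no
#' larger than `n_iter`, all of them are enumerated and the p-value is
#' exact; otherwise `n_iter` random relabellings are drawn and the add-one
#' Monte Carlo convention `p = (1 + k) / (n_iter + 1)` is used, so p is
#' never exactly zero.
#'
#' @param group_a,group_b Numeric vectors of observations (non-empty).
#' @param n_iter Number of random relabellings (50,000 by default, matching
#'   standard practice for cluster Popen comparisons).
#' @param seed Integer RNG seed (ignored for exhaustive enumeration).
#' @param statistic `"mean"` (default) or `"median"` group summary.
#'
#' @return A list of class `rand_test`: `observed_stat`, `p_value`,
#'   `n_iter` (relabellings actually used), `exhaustive`, `statistic`,
#'   `seed`.
#' @examples
#' randomization_test(c(1, 2), c(10, 11))  # exhaustive: 6 splits
#' @export
randomization_test <- function(group_a, group_b, n_iter = 50000, seed = 1,
                               statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop_data("Both groups must be non-empty.")
  }
  if (anyNA(group_a) || anyNA(group_b)) stop_data("Groups must not contain NA.")
  if (n_iter < 1) stop_param("`n_iter` must be >= 1.")
  stat_fun <- switch(statistic, mean = mean, median = median)
  observed <- abs(stat_fun(group_a) - stat_fun(group_b))
  pool <- c(group_a, group_b)
  n_a <- length(group_a)
  n <- length(pool)
  n_splits <- choose(n, n_a)
  tol <- 1e-12 * max(1, observed)
  if (n_splits <= n_iter) {
    idx <- combn(n, n_a)
    stats_all <- apply(idx, 2L, function(i) {
      abs(stat_fun(pool[i]) - stat_fun(pool[-i]))
    })
    p <- sum(stats_all >= observed - tol) / n_splits
    out <- list(observed_stat = observed, p_value = p,
                n_iter = as.integer(n_splits), exhaustive = TRUE,
                statistic = statistic, seed = NULL)
  } else {
    null_dist <- with_seed(seed, {
      .perm_null(pool, n_a, as.integer(n_iter), statistic == "median")
    })
    k <- sum(null_dist >= observed - tol)
    p <- (1 + k) / (n_iter + 1)
    out <- list(observed_stat = observed, p_value = p,
                n_iter = as.integer(n_iter), exhaustive = FALSE,
                statistic = statistic, seed = seed)
  }
  structure(out, class = "rand_test")
}

#' @export
print.rand_test <- function(x, ...) {
  cat("<rand_test>", if (x$exhaustive) "(exhaustive)" else "(Monte Carlo)", "\n")
  cat(sprintf("  |difference of group %ss| = %.4g\n", x$statistic, x$observed_stat))
  cat(sprintf("  two-tailed p = %.4g  (%d relabellings)\n", x$p_value, x$n_iter))
  invisible(x)
}

#' Tidy a randomization-test result
#'
#' @param x A `rand_test` object.
#' @param ... Unused.
#' @return A one-row tibble with `observed_stat`, `p_value`, `n_iter`,
#'   `exhaustive`, `statistic`.
#' @export
tidy.rand_test <- function(x, ...) {
  tibble::tibble(observed_stat = x$observed_stat, p_value = x$p_value,
                 n_iter = x$n_iter, exhaustive = x$exhaustive,
                 statistic = x$statistic)
}

#' Bootstrap standard deviation of a summary statistic
#'
#' Draws `n_boot` resamples with replacement (same size as the input),
#' applies the statistic, and returns the sample SD (n - 1 denominator) of
#' the replicate values together with the replicates themselves.
#'
#' @param values Numeric vector (non-empty).
#' @param statistic `"mean"` or `"median"`.
#' @param n_boot Number of bootstrap replicates (10,000 by default).
#' @param seed Integer RNG seed.
#' @return A list with `sd` and `distribution` (length `n_boot`).
#' @examples
#' bootstrap_sd(rnorm(50), n_boot = 500, seed = 1)$sd
#' @export
bootstrap_sd <- function(values, statistic = c("mean", "median"),
                         n_boot = 10000, seed = 1) {
  statistic <- match.arg(statistic)
  if (length(values) == 0L) stop_data("`values` must be non-empty.")
  if (anyNA(values)) stop_data("`values` must not contain NA.")
  if (n_boot < 1) stop_param("`n_boot` must be >= 1.")
  dist <- with_seed(seed, {
    n <- length(values)
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    m <- matrix(values[idx], nrow = n, ncol = n_boot)
    if (statistic == "mean") colMeans(m) else apply(m, 2L, median)
  })
  list(sd = sd(dist), distribution = dist)
}
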