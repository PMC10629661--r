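#' Bootstrapped group difference
#'
#' Resamples each group with replacement \code{n_boot} times and computes the
#' difference of resampled means (A minus B).  The one-sided p value is the
#' fraction of difference scores at or below zero (the convention used
#' throughout the pipeline: small p means A reliably exceeds B); a two-sided
#' version and the percentile 95\% CI are also returned.
#'
#' @param a,b numeric vectors (each with at least 5 values).
#' @param n_boot bootstrap iterations (10000).
#' @param seed integer seed.
#' @return List with \code{diff_mean}, \code{diffs} (the bootstrap
#'   distribution), \code{p_one_sided}, \code{p_two_sided}, \code{ci95}.
#' @export
bootstrap_difference <- function(a, b, n_boot = 10000, seed = 1) {
  if (length(a) < 5 || length(b) < 5)
    stop("both groups need at least 5 values")
  set.seed(seed)
  na <- length(a); nb <- length(b)
  ma <- matrix(sample(a, na * n_boot, replace = TRUE), nrow = n_boot)
  mb <- matrix(sample(b, nb * n_boot, replace = TRUE), nrow = n_boot)
  diffs <- rowMeans(ma) - rowMeans(mb)
  p1 <- mean(diffs <= 0)
  list(diff_mean = mean(a) - mean(b), diffs = diffs,
       p_one_sided = p1,
       p_two_sided = min(1, 2 * min(p1, mean(diffs >= 0))),
       ci95 = stats::quantile(diffs, c(0.025, 0.975), names = FALSE))
}

#' Bonferroni decisions
#'
#' Reject H0 for each p value iff p < alpha / m.
#'
#' @param p numeric vector of p values.
#' @param m number of comparisons (defaults to \code{length(p)}).
#' @param alpha family-wise error rate (0.05).
#' @return Logical vector of rejections.
#' @export
bonferroni_decisions <- function(p, m = length(p), alpha = 0.05) {
  stopifnot(m >= 1)
  p < alpha / m
}

# AUC of the empirical cumulative distribution of x on a fixed grid.
# Higher scores shift the CDF right and so LOWER this AUC.
ecdf_auc <- function(x, grid) {
  sx <- sort(x)
  sum(findInterval(grid, sx) / length(sx))
}

#' Compare a data score distribution with a shuffle distribution (AUC test)
#'
#' The empirical cumulative distribution of the data scores is bootstrapped
#' \code{n_boot} times; for each bootstrap the area under the CDF (its sum
#' on a fixed shared grid) is computed and differenced against the AUC of
#' the shuffle distribution.  Because higher scores lower the CDF-AUC, the
#' normalized score is reported as (shuffle AUC - data AUC): positive values
#' mean the data scores are stochastically larger (more coherent) than the
#' shuffle.  The p value is the fraction of bootstrap differences at or
#' below zero.
#'
#' @param data numeric vector of observed scores (>= 10).
#' @param shuffle numeric vector of matched shuffle scores (>= 10).
#' @param n_boot bootstrap iterations (10000).
#' @param seed integer seed.
#' @param grid evaluation grid; defaults to 101 points spanning [0, 1]
#'   (coherence scores live there) extended to the observed range if needed.
#' @return List with \code{auc_diff} (normalized AUC, shuffle - data),
#'   \code{boot_diffs}, \code{p_value}, \code{ci95}, \code{auc_data},
#'   \code{auc_shuffle}.
#' @export
auc_compare <- function(data, shuffle, n_boot = 10000, seed = 1, grid = NULL) {
  if (length(data) < 10 || length(shuffle) < 10)
    stop("need at least 10 scores in each distribution")
  if (is.null(grid)) {
    lo <- min(0, data, shuffle); hi <- max(1, data, shuffle)
    grid <- seq(lo, hi, length.out = 101)
  }
  auc_d <- ecdf_auc(data, grid)
  auc_s <- ecdf_auc(shuffle, grid)
  set.seed(seed)
  n <- length(data)
  boot <- vapply(seq_len(n_boot), function(i) {
    ecdf_auc(data[sample.int(n, n, replace = TRUE)], grid)
  }, 0)
  diffs <- auc_s - boot  # positive: data more coherent
  list(auc_diff = auc_s - auc_d, boot_diffs = diffs,
       p_value = mean(diffs <= 0),
       ci95 = stats::quantile(diffs, c(0.025, 0.975), names = FALSE),
       auc_data = auc_d, auc_shuffle = auc_s)
}
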