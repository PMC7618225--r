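#' Bootstrap test of a mean difference
#'
#' Resampled mean differences between two samples; indices are resampled
#' jointly for paired data and independently otherwise. The p-value is the
#' fraction of resamples crossing zero (doubled and capped at 1 for
#' two-sided tests).
#'
#' @param x,y numeric samples (equal length when paired).
#' @param paired paired resampling (default FALSE).
#' @param sided "two" (default), "greater" (x > y), or "less".
#' @param n resamples (default 10000; the full-scale convention is 1e5).
#' @param seed RNG seed.
#' @return list of class `bootstrap_result`: `observed`, `ci`
#'   (2.5/97.5 percentiles), `p`, `n_resamples`, `paired`, `boot`.
#' @export
bootstrap_test <- function(x, y, paired = FALSE, sided = "two",
                           n = 10000, seed = 1L) {
  if (length(x) < 2L || length(y) < 2L) stop("bootstrap_test: need >= 2 observations")
  if (paired && length(x) != length(y)) stop("bootstrap_test: paired samples must match")
  set.seed(seed)
  boot <- if (paired) {
    d <- x - y
    vapply(seq_len(n), function(i) mean(d[sample.int(length(d), replace = TRUE)]),
           numeric(1))
  } else {
    vapply(seq_len(n), function(i) {
      mean(x[sample.int(length(x), replace = TRUE)]) -
        mean(y[sample.int(length(y), replace = TRUE)])
    }, numeric(1))
  }
  lo <- mean(boot <= 0); hi <- mean(boot >= 0)
  p <- switch(sided,
              two = min(1, 2 * min(lo, hi)),
              greater = lo,
              less = hi,
              stop("bootstrap_test: sided must be 'two', 'greater' or 'less'"))
  structure(list(observed = mean(x) - mean(y),
                 ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
                 p = p, n_resamples = n, paired = paired, boot = boot),
            class = "bootstrap_result")
}

#' Bootstrap percentile confidence interval of a statistic
#'
#' @param x numeric sample (non-empty).
#' @param statistic function of a numeric vector (default mean).
#' @param n resamples (default 10000).
#' @param seed RNG seed.
#' @return list: `observed`, `ci` (2.5/97.5 percentiles), `boot`.
#' @export
bootstrap_ci <- function(x, statistic = mean, n = 10000, seed = 1L) {
  if (length(x) == 0L) stop("bootstrap_ci: empty sample")
  set.seed(seed)
  boot <- vapply(seq_len(n), function(i) {
    statistic(x[sample.int(length(x), replace = TRUE)])
  }, numeric(1))
  list(observed = statistic(x),
       ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
       boot = boot)
}
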