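#' Two-sided Mann-Whitney U test
#'
#' Thin wrapper over the rank-sum machinery fixing the package's conventions:
#' two-sided, U statistic reported for the first sample, exact null
#' distribution for small tie-free samples and the tie-corrected normal
#' approximation otherwise.
#'
#' @param x,y Numeric samples.
#' @return `list(statistic, p)` where `statistic` is U for `x` versus `y`.
#' @export
mwu_test <- function(x, y) {
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Welch two-sample t test (two-sided)
#'
#' @param x,y Numeric samples.
#' @return `list(statistic, p)`.
#' @export
welch_t_test <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value)
}

#' Kruskal-Wallis H test
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return `list(statistic, p)` with the tie-corrected H statistic.
#' @export
kw_test <- function(values, groups) {
  if (length(unique(values)) == 1L) {
    # all observations tied: no evidence of any group difference
    return(list(statistic = 0, p = 1))
  }
  kt <- stats::kruskal.test(values, as.factor(groups))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Pearson correlation coefficient
#'
#' @param x,y Numeric vectors.
#' @return Scalar r.
#' @export
pearson_r <- function(x, y) stats::cor(x, y, method = "pearson")

#' Exact two-sided binomial test by tail doubling
#'
#' P-value is twice the smaller of P(X <= k) and P(X >= k), capped at 1
#' (the doubling rule, not the minimum-likelihood rule used by
#' `binom.test`).
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p Null success probability.
#' @return `list(statistic = k, p)`.
#' @export
binom_test_two_sided <- function(k, n, p) {
  lower <- stats::pbinom(k, n, p)
  upper <- stats::pbinom(k - 1, n, p, lower.tail = FALSE)
  list(statistic = k, p = min(1, 2 * min(lower, upper)))
}

#' Percentile bootstrap of a statistic
#'
#' @param x Data (vector, or data.frame resampled by row).
#' @param stat Function of the resampled data.
#' @param n_boot Number of resamples.
#' @param seed RNG seed.
#' @param conf Confidence level for the percentile interval.
#' @return `list(sd, ci, replicates)`.
#' @export
boot_stat <- function(x, stat, n_boot = 1000L, seed = NULL, conf = 0.95) {
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  reps <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    stat(if (is.data.frame(x)) x[idx, , drop = FALSE] else x[idx])
  }, numeric(1)))
  a <- (1 - conf) / 2
  list(sd = stats::sd(reps),
       ci = unname(stats::quantile(reps, c(a, 1 - a), na.rm = TRUE)),
       replicates = reps)
}

# Bootstrap SD of median(x) - median(y), resampling both groups.
boot_median_diff <- function(x, y, n_boot = 1000L, seed = NULL) {
  reps <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    stats::median(x[sample.int(length(x), replace = TRUE)]) -
      stats::median(y[sample.int(length(y), replace = TRUE)])
  }, numeric(1)))
  stats::sd(reps)
}
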