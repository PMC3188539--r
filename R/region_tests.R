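# Rate-uniformity tests: resampling tests comparing a named region (e.g. a
# substrate-recognition loop) against the remainder of the protein, and the
# Poisson likelihood-ratio test for rate uniformity across trees.

# Shared machinery: resample same-size column subsets; exact enumeration when
# the number of subsets is small enough.
region_resample_p <- function(values, region_idx, statistic,
                              n_resample = 1e5, seed = NULL,
                              alternative = c("less", "greater", "two.sided"),
                              exact_limit = 1e5) {
  alternative <- match.arg(alternative)
  n <- length(values)
  k <- length(region_idx)
  if (k == 0L || k >= n) {
    stop("region must be a strict non-empty subset of the columns",
         call. = FALSE)
  }
  obs <- statistic(values[region_idx])
  n_subsets <- choose(n, k)
  if (n_subsets <= exact_limit) {
    stats_null <- utils::combn(n, k, function(s) statistic(values[s]))
    lo <- mean(stats_null <= obs)
    hi <- mean(stats_null >= obs)
    mode <- "exact"
  } else {
    if (!is.null(seed)) set.seed(seed)
    stats_null <- vapply(seq_len(n_resample), function(i) {
      statistic(values[sample.int(n, k)])
    }, numeric(1))
    lo <- (1 + sum(stats_null <= obs)) / (1 + n_resample)
    hi <- (1 + sum(stats_null >= obs)) / (1 + n_resample)
    mode <- "monte-carlo"
  }
  p <- switch(alternative,
              less = lo,
              greater = hi,
              two.sided = min(1, 2 * min(lo, hi)))
  list(p_value = p, statistic = obs, mode = mode)
}

#' Location test for a region's substitution counts
#'
#' Tests whether the mean per-site count in a region differs from that of
#' same-size random column sets. The default one-sided lower tail asks
#' whether the region evolves more slowly than the remainder.
#'
#' @param site_counts Numeric vector of per-column counts for one clade.
#' @param region_columns Integer indices of the region's columns (strictly
#'   inside the column set).
#' @param n_resample Monte-Carlo draws (default 100000).
#' @param seed Integer seed for Monte-Carlo mode.
#' @param alternative `"less"` (default), `"greater"` or `"two.sided"`.
#' @param exact_limit Enumerate all subsets when `choose(n, k)` is at most
#'   this (default 1e5); the p-value is then the true tail proportion.
#' @return List with `p_value`, `statistic` (region mean), `mode`.
#' @export
region_location_test <- function(site_counts, region_columns,
                                 n_resample = 1e5, seed = NULL,
                                 alternative = "less", exact_limit = 1e5) {
  region_resample_p(site_counts, region_columns, mean,
                    n_resample = n_resample, seed = seed,
                    alternative = alternative, exact_limit = exact_limit)
}

#' Rank-sum (distribution) test for a region's substitution counts
#'
#' Same resampling scheme as [region_location_test()] but with the sum of
#' mid-ranks of the region's counts as statistic, sensitive to any
#' distributional difference.
#'
#' @inheritParams region_location_test
#' @return List with `p_value`, `statistic` (region rank sum), `mode`.
#' @export
region_distribution_test <- function(site_counts, region_columns,
                                     n_resample = 1e5, seed = NULL,
                                     alternative = "less",
                                     exact_limit = 1e5) {
  ranks <- rank(site_counts)  # mid-ranks for ties
  region_resample_p(ranks, region_columns, sum,
                    n_resample = n_resample, seed = seed,
                    alternative = alternative, exact_limit = exact_limit)
}

#' Poisson likelihood-ratio test for rate uniformity across trees
#'
#' Sums of Poisson processes are Poisson, so total counts x_i over trees with
#' lengths t_i are Poisson(lambda_i t_i). Tests H0: all lambda_i equal. The
#' statistic -2 log Lambda = 2 sum x_i log(x_i / (lambda_hat t_i)) with
#' lambda_hat = sum(x)/sum(t) and 0 log 0 = 0 is asymptotically chi-square
#' with n - 1 degrees of freedom.
#'
#' @param x Non-negative counts, one per tree (n >= 2).
#' @param t Positive tree lengths, same length as `x`.
#' @return Object of class `rate_lrt`: `statistic`, `df`, `p_value`,
#'   `lambda_hat` (pooled), `lambda_i` (per tree). Has a
#'   [generics::tidy()] method.
#' @export
poisson_lrt <- function(x, t) {
  stopifnot(length(x) == length(t), length(x) >= 2L)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(t <= 0)) stop("tree lengths must be positive", call. = FALSE)
  lambda_hat <- sum(x) / sum(t)
  terms <- ifelse(x > 0, x * log(x / (lambda_hat * t)), 0)
  stat <- max(0, 2 * sum(terms))
  df <- length(x) - 1L
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  if (all(x == 0)) { stat <- 0; p <- 1 }
  structure(
    list(statistic = stat, df = df, p_value = p,
         lambda_hat = lambda_hat, lambda_i = x / t,
         x = x, t = t),
    class = "rate_lrt"
  )
}

#' @export
print.rate_lrt <- function(x, ...) {
  cat(sprintf("<rate_lrt> -2 log Lambda = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Rate-uniformity tests over replicate subtrees
#'
#' For a family containing several replicate subtrees over the same organism
#' set, tests (1) whether the whole-subtree substitution totals share one
#' Poisson rate and (2) whether the stem edges connecting the subtrees to
#' their common ancestor do.
#'
#' @param subtree_counts,subtree_lengths Totals and tree lengths per replicate
#'   subtree (named consistently).
#' @param stem_counts,stem_lengths Totals and lengths for the stem edges, in
#'   the same replicate order.
#' @return List with two [poisson_lrt()] results: `subtree`, `stem`.
#' @export
replicate_tree_rate_tests <- function(subtree_counts, subtree_lengths,
                                      stem_counts, stem_lengths) {
  if (length(subtree_counts) != length(stem_counts) ||
      length(subtree_counts) != length(subtree_lengths) ||
      length(stem_counts) != length(stem_lengths)) {
    stop("replicate vectors have mismatched lengths", call. = FALSE)
  }
  na <- names(subtree_counts); nb <- names(stem_counts)
  if (!is.null(na) && !is.null(nb) && !identical(na, nb)) {
    stop("replicate membership differs between subtree and stem inputs",
         call. = FALSE)
  }
  list(
    subtree = poisson_lrt(subtree_counts, subtree_lengths),
    stem = poisson_lrt(stem_counts, stem_lengths)
  )
}
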