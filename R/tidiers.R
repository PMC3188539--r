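# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted divergence mixture
#'
#' @param x A `theta_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.theta_fit <- function(x, ...) {
  if (x$kind == "typeII") {
    return(tibble::tibble(term = "theta", estimate = x$theta,
                          std.error = x$standard_error))
  }
  tibble::tibble(
    term = c("theta", "gamma_shape", "gamma_rate"),
    estimate = c(x$theta, x$alpha, x$beta),
    std.error = c(x$standard_error, NA_real_, NA_real_)
  )
}

#' @rdname tidy.theta_fit
#' @export
glance.theta_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    theta = x$theta,
    log_likelihood = x$log_likelihood,
    boundary = x$boundary,
    converged = identical(x$convergence, 0L) || x$convergence == 0,
    n = if (!is.null(x$column)) length(x$column) else x$n_conserved
  )
}

#' Tidy a clustering permutation test
#'
#' @param x A `cluster_test`.
#' @param ... Unused.
#' @return One-row tibble with the statistic, p-value and mode.
#' @export
tidy.cluster_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    p_value = x$p_value,
    mode = x$mode,
    pool_size = x$pool_size,
    contribution_e1 = unname(x$per_edge[1]),
    contribution_e2 = unname(x$per_edge[2])
  )
}

#' Tidy a Poisson rate-uniformity LRT
#'
#' @param x A `rate_lrt`.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `lambda_hat`.
#' @export
tidy.rate_lrt <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df,
                 p_value = x$p_value, lambda_hat = x$lambda_hat)
}

#' Tidy a parsimony search result
#'
#' @param x A `parsimony_result`.
#' @param ... Unused.
#' @return One row per character: `character`, `score`.
#' @export
tidy.parsimony_result <- function(x, ...) {
  tibble::tibble(character = names(x$per_character),
                 score = as.integer(x$per_character))
}

#' @rdname tidy.parsimony_result
#' @export
glance.parsimony_result <- function(x, ...) {
  tibble::tibble(best_score = x$best_score,
                 n_optimal = length(x$trees),
                 n_topologies = x$n_topologies,
                 lower_bound = x$lower_bound)
}
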