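# ggplot2 graphics for the main result types.

#' Scatter plot of per-site rates between two clades
#'
#' One point per aligned column, optionally coloured by site class, the
#' standard way to eyeball heterotachy between clades of orthologs.
#'
#' @param rates A [relative_rates()] table.
#' @param clade_a,clade_b Clades to plot (x and y).
#' @param calls Optional [classify_sites()] table for colouring.
#' @return A ggplot object.
#' @export
plot_rate_scatter <- function(rates, clade_a, clade_b, calls = NULL) {
  wide <- rates |>
    dplyr::filter(.data$clade %in% c(clade_a, clade_b)) |>
    tidyr::pivot_wider(names_from = "clade", values_from = "rate")
  r <- stats::cor(wide[[clade_a]], wide[[clade_b]])
  if (!is.null(calls)) {
    wide <- dplyr::left_join(wide,
                             calls[, c("column", "class")], by = "column")
  } else {
    wide$class <- factor("none", levels = c("type0", "typeI", "typeII",
                                            "none"))
  }
  ggplot2::ggplot(wide, ggplot2::aes(x = .data[[clade_a]],
                                     y = .data[[clade_b]],
                                     colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(type0 = "grey40",
                                            typeI = "forestgreen",
                                            typeII = "firebrick",
                                            none = "grey75"),
                                 drop = FALSE) +
    ggplot2::labs(
      x = paste("rate,", clade_a), y = paste("rate,", clade_b),
      subtitle = sprintf("Pearson correlation %.2f", r)
    ) +
    ggplot2::theme_minimal()
}

#' Per-column type I posterior profile
#'
#' @param posteriors A [type_I_posteriors()] table.
#' @param cutoff Posterior call cutoff drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_posterior_profile <- function(posteriors, cutoff = 0.90) {
  ggplot2::ggplot(posteriors, ggplot2::aes(x = .data$column,
                                           y = .data$posterior)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$column, yend = 0),
                          colour = "steelblue") +
    ggplot2::geom_hline(yintercept = cutoff, linetype = 2,
                        colour = "firebrick") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "alignment column",
                  y = "posterior P(type I)") +
    ggplot2::theme_minimal()
}

#' Null distribution of the clustering statistic
#'
#' @param object A `cluster_test`.
#' @param ... Unused.
#' @return A ggplot object: permutation null with the observed statistic.
#' @export
autoplot.cluster_test <- function(object, ...) {
  df <- tibble::tibble(S = object$null_stats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$S)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = object$statistic,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "clustering statistic S (null permutations)",
                  y = "count",
                  subtitle = sprintf("observed S = %d, p = %.4g (%s)",
                                     object$statistic, object$p_value,
                                     object$mode)) +
    ggplot2::theme_minimal()
}

#' Per-clade rate estimates behind a rate-uniformity LRT
#'
#' @param object A `rate_lrt`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rate_lrt <- function(object, ...) {
  nm <- names(object$x) %||% paste0("tree", seq_along(object$x))
  df <- tibble::tibble(tree = factor(nm, levels = nm),
                       rate = object$lambda_i)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tree, y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$lambda_hat, linetype = 2) +
    ggplot2::labs(x = NULL, y = "substitutions per unit tree length",
                  subtitle = sprintf("-2 log Lambda = %.2f, df = %d, p = %.3g",
                                     object$statistic, object$df,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}
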