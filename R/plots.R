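#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a precision/recall curve
#'
#' Precision against cumulative recall, the benchmark view used to compare
#' prediction methods; the dashed line marks the 0.5 precision a no-signal
#' ranking tends to under the size-matched random false-positive model.
#'
#' @param object A [precision_recall()] curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pg_pr_curve <- function(object, ...) {
  pts <- object[!is.na(object$precision), ]
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall (cumulative predicted hits)", y = "Precision",
                  title = "Precision vs recall against random models") +
    ggplot2::theme_minimal()
}

#' Plot a degree distribution with its power-law fit
#'
#' Log-log frequency histogram with the fitted regression line; a straight
#' line indicates a heavy-tailed (scale-free trend) distribution, a bell an
#' adjacency-random (Gaussian-like) one.
#'
#' @param network A `pg_network` or a [degree_histogram()] tibble.
#' @return A ggplot.
#' @export
plot_degree_distribution <- function(network) {
  hist <- if (inherits(network, "pg_network")) {
    degree_histogram(network)
  } else {
    network
  }
  fit <- tryCatch(fit_power_law(hist), error = function(e) NULL)
  p <- ggplot2::ggplot(hist, ggplot2::aes(x = .data$k, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "frequency",
                  title = "Degree distribution (log-log)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    cf <- stats::coef(fit$fit)
    p <- p + ggplot2::geom_abline(intercept = cf[1], slope = cf[2],
                                  colour = "steelblue") +
      ggplot2::labs(subtitle = sprintf("gamma = %.2f, r = %.3f",
                                       fit$gamma, fit$r))
  }
  p
}

#' Plot an intersection report against its random baselines
#'
#' @param object A [intersect_with_baselines()] result.
#' @param ... Unused.
#' @return A ggplot of %PGe for the real intersection and each null model.
#' @export
autoplot.pg_intersection <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$type, y = .data$pct_pg_backed)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "%PGe (PG edges backed by KG)",
                  title = "PG/KG overlap vs randomization nulls") +
    ggplot2::theme_minimal()
}

#' Plot the top of a dark-hub ranking
#'
#' @param object A [rank_dark_hubs()] tibble.
#' @param top_n How many top-ranked proteins to show (default 20).
#' @param ... Unused.
#' @return A ggplot comparing PG and KG degrees of the top dark hubs.
#' @export
autoplot.pg_dark_hubs <- function(object, top_n = 20, ...) {
  d <- utils::head(object, top_n)
  d <- tidyr::pivot_longer(d[, c("protein", "kg_ki", "pg_ki")],
                           c("kg_ki", "pg_ki"),
                           names_to = "network", values_to = "degree")
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$protein, -.data$degree),
                                  y = .data$degree, fill = .data$network)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "degree",
                  title = "Top dark hubs: predicted vs experimental degree") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
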