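#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted null model
#' @param x A [fit_null()] model.
#' @param ... Unused.
#' @return One-row tibble with `mu`, `sigma`, `fit_method`, `n_fit`.
#' @export
tidy.pg_null_model <- function(x, ...) {
  tibble::tibble(mu = x$mu, sigma = x$sigma, fit_method = x$fit_method,
                 n_fit = x$n_fit)
}

#' @rdname tidy.pg_null_model
#' @export
glance.pg_null_model <- function(x, ...) tidy(x)

#' Tidy optimized integration weights
#' @param x A [optimize_weights()] result.
#' @param ... Unused.
#' @return Tibble with one row per method: `method`, `weight`.
#' @export
tidy.pg_weights <- function(x, ...) {
  tibble::tibble(method = names(x$weights), weight = unname(x$weights))
}

#' One-row summary of a weight search
#' @param x A [optimize_weights()] result.
#' @param ... Unused.
#' @return Tibble with `objective_value` and `n_steps`.
#' @export
glance.pg_weights <- function(x, ...) {
  tibble::tibble(objective_value = x$objective_value,
                 n_steps = max(x$trace$step))
}

#' One-row summary of a precision/recall curve
#' @param x A [precision_recall()] curve.
#' @param ... Unused.
#' @return Tibble with `power` (area under precision-recall), `max_recall`,
#'   `n_points`, `n_random`, `n_gold`.
#' @export
glance.pg_pr_curve <- function(x, ...) {
  tibble::tibble(power = prediction_power(x), max_recall = max(x$recall),
                 n_points = nrow(x), n_random = attr(x, "n_random"),
                 n_gold = attr(x, "n_gold"))
}

#' One-row summary of a network
#' @param x A `pg_network`.
#' @param ... Unused.
#' @return Tibble with `kind`, `cutoff`, `n_edges`, `n_nodes`, `density`.
#' @export
glance.pg_network <- function(x, ...) {
  tibble::tibble(kind = attr(x, "kind"), cutoff = attr(x, "cutoff"),
                 n_edges = nrow(x), n_nodes = length(network_nodes(x)),
                 density = nrow(x) / length(network_nodes(x)))
}

#' One-row summary of a topology analysis
#' @param x A [topology_summary()] result.
#' @param ... Unused.
#' @return Tibble with the headline topology statistics.
#' @export
glance.pg_topology <- function(x, ...) {
  tibble::tibble(
    n_edges = x$n_edges, n_nodes = x$n_nodes, density = x$density,
    powerlaw_gamma = if (!is.null(x$powerlaw)) x$powerlaw$gamma else NA_real_,
    powerlaw_r = if (!is.null(x$powerlaw)) x$powerlaw$r else NA_real_,
    degree_class = if (!is.null(x$degree_class)) x$degree_class$label else NA_character_,
    avg_clustering = x$avg_clustering,
    assortativity = x$assortativity,
    char_path_length = x$distances$char_path_length,
    radius = x$distances$radius, diameter = x$distances$diameter
  )
}

#' Tidy an intersection report
#' @param x A [network_intersection()] result.
#' @param ... Unused.
#' @return Tibble with one row for the real intersection and one per baseline.
#' @export
tidy.pg_intersection <- function(x, ...) {
  real <- tibble::tibble(type = "real", n_edges_shared = x$n_edges_shared,
                         n_nodes_shared = x$n_nodes_shared,
                         density = x$density, pct_pg_backed = x$pct_pg_backed,
                         enrichment_ratio = NA_real_)
  base <- purrr::imap(x$baselines %||% list(), function(b, nm) {
    tibble::tibble(type = nm, n_edges_shared = b$n_edges_shared_mean,
                   n_nodes_shared = b$n_nodes_shared_mean,
                   density = b$density_mean,
                   pct_pg_backed = b$pct_pg_backed_mean,
                   enrichment_ratio = x$enrichment_ratios[[nm]])
  })
  dplyr::bind_rows(real, base)
}

#' @rdname tidy.pg_intersection
#' @export
glance.pg_intersection <- function(x, ...) tidy(x)[1, ]
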