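#' Degree histogram of a network
#'
#' @param network A `pg_network`.
#' @return Tibble `k` (degree), `count` (number of nodes with that degree),
#'   covering observed degrees only; `sum(k * count) == 2 * n_edges`.
#' @export
degree_histogram <- function(network) {
  stopifnot(nrow(network) > 0)
  deg <- network_degrees(network)
  tab <- table(deg)
  tibble::tibble(k = as.integer(names(tab)), count = as.integer(tab))
}

#' Power-law fit of a degree distribution
#'
#' Least-squares regression of `log10(count)` on `log10(k)` over nonzero
#' frequency classes, the conventional diagnostic for scale-free topology. The
#' returned exponent is the magnitude of the slope; real scale-free networks
#' typically show exponents between 2 and 3.
#'
#' @param degree_freq A [degree_histogram()] tibble (or a network).
#' @return List (class `pg_powerlaw_fit`): `gamma` (slope magnitude), `r`
#'   (Pearson correlation of the log-log fit), `n_points`, and the `lm` fit.
#' @export
fit_power_law <- function(degree_freq) {
  if (inherits(degree_freq, "pg_network")) {
    degree_freq <- degree_histogram(degree_freq)
  }
  pts <- degree_freq[degree_freq$count > 0 & degree_freq$k > 0, ]
  if (nrow(pts) < 3) stop("need >= 3 nonzero degree classes", call. = FALSE)
  lk <- log10(pts$k)
  lc <- log10(pts$count)
  fit <- stats::lm(lc ~ lk)
  structure(
    list(gamma = abs(unname(stats::coef(fit)[2])),
         r = if (stats::sd(lc) == 0) 0 else stats::cor(lk, lc),
         n_points = nrow(pts), fit = fit),
    class = "pg_powerlaw_fit"
  )
}

#' @export
print.pg_powerlaw_fit <- function(x, ...) {
  cat("<pg_powerlaw_fit> gamma = ", signif(x$gamma, 4), ", r = ",
      signif(x$r, 4), " (", x$n_points, " degree classes)\n", sep = "")
  invisible(x)
}

#' Clustering coefficients
#'
#' `C_i = 2 * (edges among neighbors) / (k_i * (k_i - 1))` for nodes of degree
#' at least 2, and 0 otherwise. The C(k) profile (mean C per degree class) is
#' the hierarchy diagnostic: a flat profile indicates a non-hierarchical
#' organisation, a power-law decay a hierarchical one.
#'
#' @param network A `pg_network`.
#' @return List: `local` (tibble `protein`, `k`, `c`), `average` (mean over
#'   all nodes), `by_degree` (tibble `k`, `mean_c`).
#' @export
clustering <- function(network) {
  g <- as_igraph(network)
  k <- igraph::degree(g)
  ci <- unname(igraph::transitivity(g, type = "local", isolates = "zero"))
  ci[!is.finite(ci)] <- 0
  local <- tibble::tibble(protein = igraph::V(g)$name, k = as.integer(k), c = ci)
  by_degree <- dplyr::summarise(dplyr::group_by(local, .data$k),
                                mean_c = mean(.data$c), .groups = "drop")
  list(local = local, average = mean(ci), by_degree = by_degree)
}

#' Degree assortativity
#'
#' Pearson correlation of the degrees at the two ends of edges (both
#' orientations counted). Negative values indicate hubs preferentially linking
#' to low-degree nodes, as in most biological networks.
#'
#' @param network A `pg_network`.
#' @return Correlation in \[-1, 1\]; `NA` when all edge-end degrees are equal.
#' @export
assortativity <- function(network) {
  stopifnot(nrow(network) >= 2)
  deg <- network_degrees(network)
  da <- deg[network$protein_a]
  db <- deg[network$protein_b]
  x <- c(da, db)
  y <- c(db, da)
  if (stats::sd(x) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Distance metrics on the largest component
#'
#' BFS shortest paths on the largest connected component give the
#' characteristic path length (mean pairwise distance), per-node eccentricity,
#' and the radius/diameter (min/max eccentricity).
#'
#' @param network A `pg_network`.
#' @return List (class `pg_distances`): `char_path_length`, `radius`,
#'   `diameter`, `eccentricities` (named vector), `component_size`.
#' @export
distance_metrics <- function(network) {
  g <- as_igraph(network)
  comp <- igraph::components(g)
  biggest <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == biggest))
  d <- igraph::distances(sub)
  ecc <- apply(d, 1, max)
  structure(
    list(char_path_length = mean(d[upper.tri(d)]),
         radius = as.integer(min(ecc)),
         diameter = as.integer(max(ecc)),
         eccentricities = stats::setNames(as.integer(ecc), rownames(d)),
         component_size = nrow(d)),
    class = "pg_distances"
  )
}

#' Gaussian vs heavy-tailed degree-distribution diagnostic
#'
#' Compares how well the log frequency histogram is described by a power law
#' (linear in `log k`) versus a Gaussian-type bell (quadratic in `k`), using
#' count-weighted, degrees-of-freedom-adjusted residual sums of squares on the
#' log scale.
#' Adjacency-randomized networks classify gaussian-like; preferential
#' attachment classifies heavy-tailed; near-ties are ambiguous.
#'
#' @param degree_freq A [degree_histogram()] tibble (or a network).
#' @param ratio Decision margin: the better model must beat the other by this
#'   factor in adjusted RSS (default 2).
#' @return List (class `pg_degree_test`): `label` in
#'   `c("gaussian-like", "heavy-tailed", "ambiguous")`, `rss_powerlaw`,
#'   `rss_gaussian`.
#' @export
gaussian_degree_test <- function(degree_freq, ratio = 2) {
  if (inherits(degree_freq, "pg_network")) {
    degree_freq <- degree_histogram(degree_freq)
  }
  pts <- degree_freq[degree_freq$count > 0 & degree_freq$k > 0, ]
  if (nrow(pts) < 5) stop("need >= 5 nonzero degree classes", call. = FALSE)
  lc <- log10(pts$count)
  lk <- log10(pts$k)
  k <- pts$k
  wts <- pts$count  # weight classes by node count so tail singletons
                    # do not drown the bulk of the distribution
  fit_pl <- stats::lm(lc ~ lk, weights = wts)
  fit_g <- stats::lm(lc ~ k + I(k^2), weights = wts)
  n <- nrow(pts)
  rss_pl <- sum(wts * stats::residuals(fit_pl)^2) / sum(wts) * n / max(1, n - 2)
  rss_g <- sum(wts * stats::residuals(fit_g)^2) / sum(wts) * n / max(1, n - 3)
  label <- if (rss_pl < 1e-12 && rss_g < 1e-12) {
    "ambiguous"
  } else if (rss_pl * ratio < rss_g) {
    "heavy-tailed"
  } else if (rss_g * ratio < rss_pl) {
    "gaussian-like"
  } else {
    "ambiguous"
  }
  structure(list(label = label, rss_powerlaw = rss_pl, rss_gaussian = rss_g),
            class = "pg_degree_test")
}

#' @export
print.pg_degree_test <- function(x, ...) {
  cat("<pg_degree_test> ", x$label, " (adj. RSS power-law ",
      signif(x$rss_powerlaw, 3), " vs gaussian ", signif(x$rss_gaussian, 3),
      ")\n", sep = "")
  invisible(x)
}

#' Full topology summary of a network
#'
#' Computes the degree histogram, power-law fit, clustering statistics,
#' assortativity, distance metrics, density (edges per node) and the
#' gaussian/heavy-tailed classification in one pass.
#'
#' @param network A `pg_network`.
#' @return A `pg_topology` list; see [glance.pg_topology()] for the one-row
#'   summary.
#' @export
topology_summary <- function(network) {
  hist <- degree_histogram(network)
  pl <- tryCatch(fit_power_law(hist), error = function(e) NULL)
  gt <- tryCatch(gaussian_degree_test(hist), error = function(e) NULL)
  cl <- clustering(network)
  dm <- distance_metrics(network)
  structure(
    list(degree_frequency = hist,
         powerlaw = pl,
         degree_class = gt,
         avg_clustering = cl$average,
         clustering_by_degree = cl$by_degree,
         assortativity = assortativity(network),
         distances = dm,
         n_edges = nrow(network),
         n_nodes = length(network_nodes(network)),
         density = nrow(network) / length(network_nodes(network))),
    class = "pg_topology"
  )
}

#' @export
print.pg_topology <- function(x, ...) {
  cat("<pg_topology> ", x$n_edges, " edges / ", x$n_nodes, " nodes",
      " (density ", round(x$density, 2), ")\n", sep = "")
  if (!is.null(x$powerlaw)) {
    cat("  power-law gamma ", signif(x$powerlaw$gamma, 3), " (r ",
        signif(x$powerlaw$r, 3), "); class ",
        if (!is.null(x$degree_class)) x$degree_class$label else "n/a",
        "\n", sep = "")
  }
  cat("  avg clustering ", signif(x$avg_clustering, 3), ", assortativity ",
      signif(x$assortativity, 3), "\n", sep = "")
  cat("  path length ", signif(x$distances$char_path_length, 3), ", radius ",
      x$distances$radius, ", diameter ", x$distances$diameter, "\n", sep = "")
  invisible(x)
}
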