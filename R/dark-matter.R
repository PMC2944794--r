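#' Intersection of a Predictogram and a Knowledgegram
#'
#' Shared edges are matched by canonical-pair equality; shared nodes are the
#' endpoints of shared edges; density is edges per node of the intersection;
#' %PGe is the percentage of PG edges backed by the KG.
#'
#' @param pg,kg `pg_network` objects (non-empty).
#' @return A `pg_intersection` list: `n_edges_shared`, `n_nodes_shared`,
#'   `density`, `pct_pg_backed`, plus `baselines`/`enrichment_ratios` slots
#'   filled by [intersect_with_baselines()].
#' @export
network_intersection <- function(pg, kg) {
  stopifnot(nrow(pg) > 0, nrow(kg) > 0)
  kg_keys <- pair_key(kg$protein_a, kg$protein_b)
  shared <- pg[pair_key(pg$protein_a, pg$protein_b) %in% kg_keys, ]
  n_edges <- nrow(shared)
  n_nodes <- length(unique(c(shared$protein_a, shared$protein_b)))
  structure(
    list(n_edges_shared = n_edges,
         n_nodes_shared = n_nodes,
         density = if (n_nodes > 0) n_edges / n_nodes else 0,
         pct_pg_backed = 100 * n_edges / nrow(pg),
         baselines = NULL, enrichment_ratios = NULL),
    class = "pg_intersection"
  )
}

#' @export
print.pg_intersection <- function(x, ...) {
  cat("<pg_intersection> ", x$n_edges_shared, " shared edges / ",
      x$n_nodes_shared, " nodes (density ", round(x$density, 2),
      "); %PGe = ", round(x$pct_pg_backed, 2), "\n", sep = "")
  if (!is.null(x$baselines)) {
    for (nm in names(x$baselines)) {
      b <- x$baselines[[nm]]
      cat("  ", nm, " null: %PGe ", round(b$pct_pg_backed_mean, 3), " +/- ",
          round(b$pct_pg_backed_sd, 3), "; enrichment ratio ",
          round(x$enrichment_ratios[[nm]], 2), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Intersection with randomization baselines
#'
#' The random baselines re-run the whole cut-and-intersect procedure after
#' randomizing the *full* weighted matrices: weights (p-values / evidence
#' counts) are shuffled over all scored pairs, or endpoints redrawn uniformly
#' over the node universe, then the PG and KG cutoffs are re-applied and the
#' cut networks intersected. The enrichment ratio is the real %PGe divided by
#' the baseline mean %PGe.
#'
#' @param pg_full Full PG network (all scored pairs, i.e. built at cutoff 1)
#'   with integrated p-values as weights.
#' @param kg_full Full KG network (min_evidence 1) with evidence counts as
#'   weights.
#' @param pg_cutoff p-value cutoff defining the analysed PG.
#' @param kg_min_evidence Evidence cutoff defining the analysed KG.
#' @param null `"weights"` (p-values random model) or `"adjacency"`.
#' @param iterations Randomization iterations (default 1000).
#' @param seed Integer seed.
#' @return A `pg_intersection` with `baselines[[null]]` (mean and sd of each
#'   statistic over iterations) and `enrichment_ratios[[null]]` (Inf if the
#'   baseline %PGe is 0).
#' @export
intersect_with_baselines <- function(pg_full, kg_full, pg_cutoff,
                                     kg_min_evidence,
                                     null = c("weights", "adjacency"),
                                     iterations = 1000, seed = NULL) {
  null <- match.arg(null)
  cut_pg <- function(net) {
    e <- net[net$weight <= pg_cutoff, ]
    if (nrow(e) == 0) NULL else new_network(e, "PG", pg_cutoff)
  }
  cut_kg <- function(net) {
    e <- net[net$weight >= kg_min_evidence, ]
    if (nrow(e) == 0) NULL else new_network(e, "KG", kg_min_evidence)
  }
  pg <- cut_pg(pg_full)
  kg <- cut_kg(kg_full)
  if (is.null(pg) || is.null(kg)) {
    stop("cutoffs leave an empty PG or KG network", call. = FALSE)
  }
  real <- network_intersection(pg, kg)
  randomizer <- if (null == "weights") randomize_weights else randomize_adjacency
  stats <- with_seed(seed, {
    purrr::map(seq_len(iterations), function(i) {
      pg_r <- cut_pg(randomizer(pg_full, seed = NULL))
      kg_r <- cut_kg(randomizer(kg_full, seed = NULL))
      if (is.null(pg_r) || is.null(kg_r)) {
        return(tibble::tibble(n_edges_shared = 0, n_nodes_shared = 0,
                              density = 0, pct_pg_backed = 0))
      }
      x <- network_intersection(pg_r, kg_r)
      tibble::tibble(n_edges_shared = x$n_edges_shared,
                     n_nodes_shared = x$n_nodes_shared,
                     density = x$density, pct_pg_backed = x$pct_pg_backed)
    })
  })
  stats <- dplyr::bind_rows(stats)
  baseline <- list(
    n_edges_shared_mean = mean(stats$n_edges_shared),
    n_edges_shared_sd = stats::sd(stats$n_edges_shared),
    n_nodes_shared_mean = mean(stats$n_nodes_shared),
    density_mean = mean(stats$density),
    pct_pg_backed_mean = mean(stats$pct_pg_backed),
    pct_pg_backed_sd = stats::sd(stats$pct_pg_backed),
    iterations = iterations
  )
  real$baselines <- stats::setNames(list(baseline), null)
  real$enrichment_ratios <- stats::setNames(
    list(if (baseline$pct_pg_backed_mean > 0) {
      real$pct_pg_backed / baseline$pct_pg_backed_mean
    } else {
      Inf
    }), null
  )
  real
}

#' Dark-node fraction of a Predictogram
#'
#' The percentage of PG nodes with zero degree in the KG: predicted proteins
#' with no experimentally supported association at all.
#'
#' @param pg,kg `pg_network` objects (`pg` non-empty).
#' @return Percentage in \[0, 100\].
#' @export
dark_node_fraction <- function(pg, kg) {
  stopifnot(nrow(pg) > 0)
  pg_nodes <- network_nodes(pg)
  dark <- setdiff(pg_nodes, network_nodes(kg))
  100 * length(dark) / length(pg_nodes)
}

#' Rank dark hubs by degree enrichment
#'
#' For every PG node, the enrichment ratio
#' `PGki_er = (PGki - KGki) / (KGki + 1)` contrasts its predicted degree with
#' its experimental degree (`KGki = 0` for proteins absent from the KG). High
#' values flag dark hubs: proteins with many predicted partners and few or no
#' experimentally validated ones. Ties are broken by protein identifier for a
#' deterministic ranking.
#'
#' @param pg,kg `pg_network` objects.
#' @return A `pg_dark_hubs` tibble: `protein`, `kg_ki`, `pg_ki`, `pg_ki_er`,
#'   `rank` (1-based, descending `pg_ki_er`).
#' @export
rank_dark_hubs <- function(pg, kg) {
  pg_deg <- network_degrees(pg)
  kg_deg <- network_degrees(kg)
  kg_ki <- kg_deg[names(pg_deg)]
  kg_ki[is.na(kg_ki)] <- 0L
  out <- tibble::tibble(
    protein = names(pg_deg),
    kg_ki = as.integer(kg_ki),
    pg_ki = as.integer(pg_deg),
    pg_ki_er = (as.numeric(pg_deg) - as.numeric(kg_ki)) / (as.numeric(kg_ki) + 1)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$pg_ki_er), .data$protein)
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("pg_dark_hubs", class(out)))
}

#' Ranked-list hypergeometric functional enrichment
#'
#' For each ontology term, tests whether the top of a ranked protein list is
#' enriched in proteins annotated (after upward propagation) to the term:
#' `E = (b/n) / (B/N)` with the hypergeometric tail probability
#' `P(X >= b | N, B, n)`. With `top_n = NULL` the cutoff is flexible: every
#' prefix of the list is scanned and the minimum tail probability with its
#' optimal `n` is reported (a simplified minimum-hypergeometric score, without
#' the exact multiple-cutoff correction).
#'
#' @param ranked_proteins Character vector, most interesting first (e.g. the
#'   `protein` column of [rank_dark_hubs()]).
#' @param annotations Tibble `protein`, `term`.
#' @param ontology A `pg_ontology`.
#' @param top_n Fixed cutoff, or NULL for the flexible scan.
#' @param significance_threshold Keep terms with tail probability at or below
#'   this (default 1e-9, the conventional screen for ranked-list surveys);
#'   `Inf` keeps all terms.
#' @return Tibble `term`, `p_value`, `N`, `B`, `n`, `b`, `enrichment`, sorted
#'   by `p_value`.
#' @export
ranked_enrichment <- function(ranked_proteins, annotations, ontology,
                              top_n = NULL, significance_threshold = 1e-9) {
  stopifnot(length(ranked_proteins) > 0, !anyDuplicated(ranked_proteins))
  prop <- propagate_annotations(annotations, ontology)
  prop <- prop[prop$protein %in% ranked_proteins, ]
  n_total <- length(ranked_proteins)
  rank_of <- stats::setNames(seq_len(n_total), ranked_proteins)
  by_term <- split(rank_of[prop$protein], prop$term)
  rows <- purrr::imap(by_term, function(ranks, term) {
    b_total <- length(ranks)
    if (b_total == 0) return(NULL)
    if (!is.null(top_n)) {
      n <- top_n
      b <- sum(ranks <= n)
      p <- stats::phyper(b - 1, b_total, n_total - b_total, n,
                         lower.tail = FALSE)
    } else {
      ns <- sort(unique(ranks))
      bs <- seq_along(ns)
      ps <- stats::phyper(bs - 1, b_total, n_total - b_total, ns,
                          lower.tail = FALSE)
      best <- which.min(ps)
      n <- ns[best]
      b <- bs[best]
      p <- ps[best]
    }
    tibble::tibble(term = term, p_value = p, N = n_total, B = b_total,
                   n = n, b = b,
                   enrichment = enrichment_ratio(n_total, b_total, n, b))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$p_value <= significance_threshold, ]
  dplyr::arrange(out, .data$p_value)
}

#' Enrichment ratio E = (b/n) / (B/N)
#'
#' @param N Total ranked genes.
#' @param B Term-annotated genes in the whole list.
#' @param n Genes in the selected top.
#' @param b Term-annotated genes in the top.
#' @return The enrichment ratio (0 when `b = 0`).
#' @export
enrichment_ratio <- function(N, B, n, b) {
  stopifnot(b <= n, B <= N, n <= N)
  if (B == 0 || n == 0) return(NA_real_)
  (b / n) / (B / N)
}
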