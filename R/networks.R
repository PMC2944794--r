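#' Network constructor
#'
#' A network is a classed tibble of canonical weighted edges plus metadata:
#' `kind` (PG, KG or random), the defining `cutoff` and the node set (edge
#' endpoints; isolated proteins are not network nodes).
#'
#' @param edges Tibble `protein_a`, `protein_b`, `weight` (canonical pairs).
#' @param kind `"PG"`, `"KG"` or `"random"`.
#' @param cutoff The threshold that defined the network (p-value cutoff for
#'   PG, minimum evidence for KG).
#' @return A `pg_network` tibble.
#' @export
new_network <- function(edges, kind = c("PG", "KG", "random"), cutoff = NA) {
  kind <- match.arg(kind)
  edges <- canonicalize_pairs(tibble::as_tibble(edges), quiet = TRUE)
  stopifnot(all(c("protein_a", "protein_b", "weight") %in% names(edges)))
  keys <- pair_key(edges$protein_a, edges$protein_b)
  if (anyDuplicated(keys)) stop("duplicate edges in network", call. = FALSE)
  edges <- dplyr::arrange(edges, .data$protein_a, .data$protein_b)
  structure(edges, kind = kind, cutoff = cutoff,
            nodes = sort(unique(c(edges$protein_a, edges$protein_b))),
            class = c("pg_network", class(edges)))
}

#' Nodes of a network
#' @param network A `pg_network`.
#' @return Sorted character vector of edge endpoints.
#' @export
network_nodes <- function(network) attr(network, "nodes")

#' Node degrees of a network
#' @param network A `pg_network`.
#' @return Named integer vector over the network's nodes.
#' @export
network_degrees <- function(network) {
  tab <- table(c(network$protein_a, network$protein_b))
  deg <- stats::setNames(as.integer(tab), names(tab))
  deg[network_nodes(network)]
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network[, c("protein_a", "protein_b")], directed = FALSE,
    vertices = network_nodes(network)
  )
}

#' Build a Predictogram at a p-value cutoff
#'
#' Retains integrated predictions with `integrated_pvalue <= pvalue_cutoff`;
#' edge weight is the integrated p-value. A network built at cutoff 0.01 is
#' conventionally written PG_0.01.
#'
#' @param integrated A [integrate_predictions()] result (or any tibble with
#'   `protein_a`, `protein_b`, `integrated_pvalue`).
#' @param pvalue_cutoff Cutoff in (0, 1].
#' @return A `pg_network` of kind PG.
#' @export
build_pg <- function(integrated, pvalue_cutoff) {
  stopifnot(pvalue_cutoff > 0, pvalue_cutoff <= 1)
  keep <- integrated$integrated_pvalue <= pvalue_cutoff
  edges <- tibble::tibble(
    protein_a = integrated$protein_a[keep],
    protein_b = integrated$protein_b[keep],
    weight = integrated$integrated_pvalue[keep]
  )
  new_network(edges, "PG", pvalue_cutoff)
}

#' Build a Knowledgegram from evidence resources
#'
#' The evidence count of an edge is the number of distinct *dependency groups*
#' reporting it: resources mapped to the same group (e.g. two ontology-derived
#' semantic-similarity sets) contribute at most one evidence between them.
#' Edges with at least `min_evidence` independent evidences are retained, with
#' the count as weight.
#'
#' @param evidence_datasets Named list of pair tibbles; each may carry a
#'   `dependency_group` attribute (see [generate_evidence_datasets()]).
#' @param min_evidence Minimum independent evidence count (default 1).
#' @param merge_groups Optional named character vector resource -> group,
#'   overriding the datasets' own group attributes.
#' @return A `pg_network` of kind KG.
#' @export
build_kg <- function(evidence_datasets, min_evidence = 1, merge_groups = NULL) {
  stopifnot(length(evidence_datasets) >= 1, min_evidence >= 1)
  nms <- names(evidence_datasets)
  if (is.null(nms)) nms <- paste0("resource", seq_along(evidence_datasets))
  group_of <- vapply(seq_along(evidence_datasets), function(i) {
    if (!is.null(merge_groups) && nms[i] %in% names(merge_groups)) {
      merge_groups[[nms[i]]]
    } else {
      attr(evidence_datasets[[i]], "dependency_group") %||% nms[i]
    }
  }, character(1))
  per_resource <- purrr::map2(evidence_datasets, group_of, function(d, g) {
    d <- canonicalize_pairs(tibble::as_tibble(d), quiet = TRUE)
    tibble::tibble(protein_a = d$protein_a, protein_b = d$protein_b, group = g)
  })
  counts <- dplyr::bind_rows(per_resource)
  counts <- dplyr::distinct(counts)
  counts <- dplyr::count(counts, .data$protein_a, .data$protein_b,
                         name = "weight")
  edges <- counts[counts$weight >= min_evidence, ]
  new_network(edges, "KG", min_evidence)
}

#' Weight-randomized null (p-values random model)
#'
#' Permutes the edge weights uniformly while keeping the connected node pairs
#' fixed: the weight multiset and the topology are both preserved exactly.
#'
#' @param network A `pg_network`.
#' @param seed Integer seed.
#' @return A `pg_network` of kind random.
#' @export
randomize_weights <- function(network, seed = NULL) {
  stopifnot(nrow(network) > 0)
  out <- with_seed(seed, {
    w <- network$weight[sample.int(nrow(network))]
    tibble::tibble(protein_a = network$protein_a,
                   protein_b = network$protein_b, weight = w)
  })
  new_network(out, "random", attr(network, "cutoff"))
}

#' Adjacency-randomized null (adjacency random model)
#'
#' Redraws both endpoints of every edge uniformly over the node set and
#' reattaches the weights in random order; self-pairs produced by the redraw
#' are removed and duplicate pairs collapsed (first drawn weight kept), so the
#' realized edge count may drop slightly. With `method = "degree_preserving"`
#' a double-edge-swap rewiring that keeps the degree sequence is used instead.
#'
#' @param network A `pg_network`.
#' @param seed Integer seed.
#' @param method `"uniform"` (default) or `"degree_preserving"`.
#' @return A `pg_network` of kind random.
#' @export
randomize_adjacency <- function(network, seed = NULL,
                                method = c("uniform", "degree_preserving")) {
  method <- match.arg(method)
  stopifnot(nrow(network) > 0)
  nodes <- network_nodes(network)
  m <- nrow(network)
  out <- with_seed(seed, {
    if (method == "uniform") {
      a <- nodes[sample.int(length(nodes), m, replace = TRUE)]
      b <- nodes[sample.int(length(nodes), m, replace = TRUE)]
      w <- network$weight[sample.int(m)]
      e <- tibble::tibble(protein_a = pmin(a, b), protein_b = pmax(a, b),
                          weight = w)
      e <- e[e$protein_a != e$protein_b, ]
      e[!duplicated(pair_key(e$protein_a, e$protein_b)), ]
    } else {
      g <- igraph::rewire(as_igraph(network),
                          igraph::keeping_degseq(niter = 10 * m))
      el <- igraph::as_edgelist(g)
      tibble::tibble(protein_a = pmin(el[, 1], el[, 2]),
                     protein_b = pmax(el[, 1], el[, 2]),
                     weight = network$weight[sample.int(nrow(network))])
    }
  })
  new_network(out, "random", attr(network, "cutoff"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pg_network <- function(x, ...) {
  cat("<pg_network ", attr(x, "kind"), "> ", nrow(x), " edges over ",
      length(network_nodes(x)), " nodes (cutoff ", attr(x, "cutoff"), ")\n",
      sep = "")
  NextMethod()
}
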