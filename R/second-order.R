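#' Interaction-profile similarity scores for node pairs
#'
#' Second-order predictions: two proteins sharing much of their interaction
#' neighborhood in a reliable predicted network are themselves likely
#' associated. For a pair, `b1` is the number of shared neighbors and `b2` the
#' number of non-shared neighbors (the symmetric difference of the two
#' neighbor sets, each excluding the other protein of the pair). The scores:
#' `bits = b1`; `specific_bits = b1 * (-log(b1 / (b1 + b2)))` (natural log by
#' default); `congruence = -log10 P(X >= b1)` under the hypergeometric model
#' of drawing one neighbor set at random from the other's potential partners.
#'
#' @param network A `pg_network`.
#' @param min_share_fraction Keep pairs sharing at least this fraction of
#'   their combined neighborhood, `b1 / (b1 + b2)` (default 1/3). The
#'   alternative reading `b1 >= min(k1, k2) / 3` is available via
#'   `share_rule = "min_degree"`.
#' @param exclude_adjacent Drop pairs already linked in the network (default
#'   TRUE: second-order predictions are *additional* pairs).
#' @param congruence Also compute the congruence score (combinatorially the
#'   most expensive of the three).
#' @param log_base Base of the log in `specific_bits` (default `exp(1)`; only
#'   the ranking matters for validation).
#' @param share_rule `"union"` (default) or `"min_degree"`, see above.
#' @return A `pg_profile_similarity` tibble: `protein_a`, `protein_b`, `b1`,
#'   `b2`, `bits`, `specific_bits` and (optionally) `congruence`.
#' @export
second_order_scores <- function(network, min_share_fraction = 1/3,
                                exclude_adjacent = TRUE, congruence = TRUE,
                                log_base = exp(1),
                                share_rule = c("union", "min_degree")) {
  share_rule <- match.arg(share_rule)
  stopifnot(nrow(network) > 0)
  nodes <- network_nodes(network)
  n <- length(nodes)
  ia <- match(network$protein_a, nodes)
  ib <- match(network$protein_b, nodes)
  adj <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia), x = 1,
                              dims = c(n, n))
  deg <- Matrix::rowSums(adj)
  common <- Matrix::triu(adj %*% adj, k = 1)
  cand <- Matrix::summary(common)
  cand <- cand[cand$x >= 1, , drop = FALSE]
  i <- cand$i
  j <- cand$j
  b1 <- cand$x
  a_ij <- as.numeric(adj[cbind(i, j)])
  k1 <- deg[i] - a_ij   # neighbor set sizes, each excluding the other protein
  k2 <- deg[j] - a_ij
  b2 <- k1 + k2 - 2 * b1
  keep <- if (share_rule == "union") {
    b1 / (b1 + b2) >= min_share_fraction
  } else {
    b1 >= pmin(k1, k2) * min_share_fraction
  }
  if (exclude_adjacent) keep <- keep & a_ij == 0
  i <- i[keep]; j <- j[keep]; b1 <- b1[keep]; b2 <- b2[keep]
  k1 <- k1[keep]; k2 <- k2[keep]
  out <- tibble::tibble(
    protein_a = pmin(nodes[i], nodes[j]),
    protein_b = pmax(nodes[i], nodes[j]),
    b1 = as.integer(b1), b2 = as.integer(b2),
    bits = as.integer(b1),
    specific_bits = b1 * (-log(b1 / (b1 + b2), base = log_base))
  )
  if (congruence) {
    out$congruence <- congruence_score(b1, k1, k2, n)
  }
  out <- dplyr::arrange(out, .data$protein_a, .data$protein_b)
  structure(out, class = c("pg_profile_similarity", class(out)))
}

# -log10 hypergeometric upper tail of sharing >= b1 neighbors when one
# protein's k1 partners are drawn from the m - 2 potential partners of which
# k2 are the other protein's neighbors.
congruence_score <- function(b1, k1, k2, n_nodes) {
  p <- stats::phyper(b1 - 1, k2, pmax(n_nodes - 2 - k2, 0), k1,
                     lower.tail = FALSE)
  -log10(pmax(p, .Machine$double.xmin))
}

#' Candidate pairs by neighborhood sharing
#'
#' All unordered node pairs (adjacent or not) with at least one shared
#' neighbor and a shared fraction `b1 / (b1 + b2)` at or above the cutoff.
#'
#' @inheritParams second_order_scores
#' @return Tibble of canonical pairs with `b1`, `b2`.
#' @export
candidate_pairs <- function(network, min_share_fraction = 1/3) {
  sc <- second_order_scores(network, min_share_fraction,
                            exclude_adjacent = FALSE, congruence = FALSE)
  sc[, c("protein_a", "protein_b", "b1", "b2")]
}

# Neighbor sets for a single pair, each excluding the other protein.
pair_neighbor_sets <- function(network, protein_1, protein_2) {
  nodes <- network_nodes(network)
  if (!protein_1 %in% nodes || !protein_2 %in% nodes) {
    stop("protein absent from the network", call. = FALSE)
  }
  nbr <- function(p) {
    unique(c(network$protein_b[network$protein_a == p],
             network$protein_a[network$protein_b == p]))
  }
  list(n1 = setdiff(nbr(protein_1), protein_2),
       n2 = setdiff(nbr(protein_2), protein_1))
}

#' Shared-neighbor count (bits score) of one pair
#' @param network A `pg_network`.
#' @param protein_1,protein_2 Protein identifiers present in the network.
#' @return `b1`, the number of shared neighbors.
#' @export
pair_bits <- function(network, protein_1, protein_2) {
  ns <- pair_neighbor_sets(network, protein_1, protein_2)
  length(intersect(ns$n1, ns$n2))
}

#' Specific-bits score of one pair
#' @inheritParams pair_bits
#' @param log_base Base of the log (default natural).
#' @return `b1 * (-log(b1 / (b1 + b2)))`; 0 when `b1 = 0` (convention) or
#'   `b2 = 0` (log 1).
#' @export
pair_specific_bits <- function(network, protein_1, protein_2,
                               log_base = exp(1)) {
  ns <- pair_neighbor_sets(network, protein_1, protein_2)
  b1 <- length(intersect(ns$n1, ns$n2))
  b2 <- length(union(ns$n1, ns$n2)) - b1
  if (b1 == 0) return(0)
  b1 * (-log(b1 / (b1 + b2), base = log_base))
}

#' Congruence score of one pair
#' @inheritParams pair_bits
#' @return `-log10` of the hypergeometric probability of sharing at least
#'   `b1` neighbors given the two degrees and the network size.
#' @export
pair_congruence <- function(network, protein_1, protein_2) {
  ns <- pair_neighbor_sets(network, protein_1, protein_2)
  b1 <- length(intersect(ns$n1, ns$n2))
  congruence_score(b1, length(ns$n1), length(ns$n2),
                   length(network_nodes(network)))
}

#' Validate second-order predictions against KG gold standards
#'
#' Ranks the scored pairs by decreasing similarity and benchmarks them against
#' the set of pairs supported by at least `min_kg_evidence` independent
#' evidence groups, using the random-model precision/recall machinery; points
#' with unstable random FP estimates (sd > mean/3) are dropped.
#'
#' @param scored_pairs A [second_order_scores()] tibble.
#' @param evidence_datasets Named list of evidence pair tibbles (see
#'   [build_kg()]).
#' @param score Which similarity column ranks the pairs (default
#'   `"specific_bits"`).
#' @param min_kg_evidence Minimum independent evidence count for the gold set
#'   (default 2).
#' @param n_random Random models (default 1000).
#' @param seed Integer seed.
#' @param node_universe Random-pair universe; defaults to the union of scored
#'   and gold endpoints.
#' @param drop_unstable Apply the sd > mean/3 stability filter (default TRUE;
#'   note that with few scored pairs the random FP counts are Poisson-small
#'   and the filter can legitimately remove every point).
#' @return A `pg_pr_curve` (threshold column on the similarity-score scale).
#' @export
validate_second_order <- function(scored_pairs, evidence_datasets,
                                  score = "specific_bits",
                                  min_kg_evidence = 2, n_random = 1000,
                                  seed = NULL, node_universe = NULL,
                                  drop_unstable = TRUE) {
  stopifnot(score %in% names(scored_pairs))
  gold_net <- build_kg(evidence_datasets, min_evidence = min_kg_evidence)
  if (nrow(gold_net) == 0) stop("empty gold standard", call. = FALSE)
  ranked <- scored_pairs[, c("protein_a", "protein_b", score)]
  names(ranked)[3] <- "score"
  curve <- precision_recall(ranked, gold_net, node_universe = node_universe,
                            n_random = n_random, seed = seed,
                            direction = "descending")
  if (drop_unstable) filter_unstable(curve) else curve
}
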