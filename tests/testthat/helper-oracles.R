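# Independent brute-force implementations used as oracles against the
# package's (igraph- or closed-form-backed) routines on small instances.

edges_to_adj <- function(edges) {
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  n <- length(nodes)
  adj <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$protein_a[r], nodes)
    j <- match(edges$protein_b[r], nodes)
    adj[i, j] <- adj[j, i] <- 1L
  }
  adj
}

brute_degrees <- function(edges) rowSums(edges_to_adj(edges))

brute_clustering <- function(edges) {
  adj <- edges_to_adj(edges)
  n <- nrow(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- sum(adj[nb, nb]) / 2
    ci[i] <- 2 * links / (k * (k - 1))
  }
  stats::setNames(ci, rownames(adj))
}

# Floyd-Warshall all-pairs shortest paths (single component assumed).
brute_distances <- function(edges) {
  adj <- edges_to_adj(edges)
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d
}

brute_assortativity <- function(edges) {
  deg <- brute_degrees(edges)
  da <- deg[edges$protein_a]
  db <- deg[edges$protein_b]
  stats::cor(c(da, db), c(db, da))
}

# Resnik by exhaustive common-ancestor enumeration over term pairs.
brute_resnik <- function(p1, p2, annotations, ontology) {
  anc <- ontology_ancestors(ontology)
  ic_tab <- term_information_content(annotations, ontology)
  ic_of <- stats::setNames(ic_tab$ic, ic_tab$term)
  t1 <- annotations$term[annotations$protein == p1]
  t2 <- annotations$term[annotations$protein == p2]
  if (length(t1) == 0 || length(t2) == 0) return(NA_real_)
  best <- 0
  for (a in t1) {
    for (b in t2) {
      common <- intersect(anc[[a]], anc[[b]])
      if (length(common) > 0) {
        best <- max(best, max(ic_of[common], 0, na.rm = TRUE))
      }
    }
  }
  best
}

# Hypergeometric upper tail P(X >= q) by direct enumeration with choose().
brute_hyper_tail <- function(q, n_white, n_black, n_draw) {
  xs <- q:min(n_white, n_draw)
  xs <- xs[xs >= max(0, n_draw - n_black)]
  if (length(xs) == 0) return(0)
  sum(choose(n_white, xs) * choose(n_black, n_draw - xs)) /
    choose(n_white + n_black, n_draw)
}

# Shared/non-shared neighbor counts by explicit set operations.
brute_profile <- function(edges, p1, p2) {
  adj <- edges_to_adj(edges)
  nb <- function(p) rownames(adj)[adj[p, ] == 1]
  n1 <- setdiff(nb(p1), p2)
  n2 <- setdiff(nb(p2), p1)
  b1 <- length(intersect(n1, n2))
  b2 <- length(union(n1, n2)) - b1
  list(b1 = b1, b2 = b2)
}

# 2x2 mutual information (bits) of two binary membership vectors.
brute_binary_mi <- function(x, y) {
  tab <- table(factor(x, c(FALSE, TRUE)), factor(y, c(FALSE, TRUE))) / length(x)
  px <- rowSums(tab)
  py <- colSums(tab)
  s <- 0
  for (i in 1:2) {
    for (j in 1:2) {
      if (tab[i, j] > 0) s <- s + tab[i, j] * log2(tab[i, j] / (px[i] * py[j]))
    }
  }
  s
}

as_igraph_oracle <- function(net) {
  igraph::graph_from_data_frame(net[, c("protein_a", "protein_b")],
                                directed = FALSE)
}

as_net <- function(edges, weight = 1, kind = "PG", cutoff = 1) {
  edges$weight <- weight
  new_network(edges, kind, cutoff)
}

pairs_tbl <- function(a, b, ...) {
  tibble::tibble(protein_a = pmin(a, b), protein_b = pmax(a, b), ...)
}
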