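#' Generate a planted true association network
#'
#' Creates a synthetic "universe" of protein functional associations against
#' which predictors, evidence resources and downstream network analyses can be
#' evaluated. The default generator is preferential attachment, which plants a
#' heavy-tailed degree distribution as observed in real biological networks; an
#' Erdos-Renyi control with Poisson (Gaussian-like) degrees is also available.
#'
#' @param n_proteins Number of proteins (>= 10).
#' @param mean_degree Target mean node degree; may be fractional.
#' @param model `"pa"` for preferential attachment (default) or `"er"` for the
#'   Erdos-Renyi control.
#' @param attachment_power Preferential-attachment kernel exponent (1 = linear,
#'   the classic Barabasi-Albert regime with asymptotic degree exponent 3).
#' @param clustering_strength Probability, per attachment edge, of adding one
#'   triangle-closing chord. Real interactomes combine a heavy-tailed degree
#'   distribution with high clustering; plain preferential attachment plants
#'   only the former, triadic closure adds the latter. 0 disables it.
#' @param n_complexes,complex_size Optionally plant this many protein
#'   complexes as near-cliques over disjoint random protein sets, on top of
#'   the attachment backbone. Complexes are the dominant source of clustering
#'   in real interactomes (co-complex membership is what pathway and
#'   interaction databases largely record); planting them raises average
#'   clustering far beyond what triadic closure alone reaches.
#' @param seed Integer seed; fixing it fixes the generated network exactly.
#' @return A `pg_world` object: a list with `proteins` (character vector),
#'   `true_edges` (canonical pair tibble), the generator parameters, and slots
#'   `ontology`/`annotations` filled by [generate_ontology()].
#' @examples
#' w <- generate_true_network(100, mean_degree = 4, seed = 1)
#' nrow(w$true_edges)
#' @export
generate_true_network <- function(n_proteins, mean_degree = 2,
                                  model = c("pa", "er"),
                                  attachment_power = 1,
                                  clustering_strength = 0,
                                  n_complexes = 0, complex_size = 8,
                                  seed = NULL) {
  model <- match.arg(model)
  if (n_proteins < 10) stop("n_proteins must be >= 10", call. = FALSE)
  if (mean_degree <= 0) stop("mean_degree must be positive", call. = FALSE)
  width <- max(4L, nchar(as.character(n_proteins)))
  proteins <- sprintf(paste0("P%0", width, "d"), seq_len(n_proteins))
  g <- with_seed(seed, {
    g <- if (model == "pa") {
      # per-node attachment counts realise a fractional mean degree:
      # each arriving node brings floor/ceil(mean_degree / 2) edges
      m_target <- mean_degree / 2
      base <- floor(m_target)
      extra <- stats::rbinom(n_proteins - 1, 1, m_target - base)
      out_seq <- c(0, base + extra)
      igraph::sample_pa(n_proteins, power = attachment_power,
                        out.seq = out_seq, zero.appeal = 1,
                        directed = FALSE)
    } else {
      m <- round(n_proteins * mean_degree / 2)
      igraph::sample_gnm(n_proteins, m)
    }
    if (n_complexes > 0) {
      # sizes vary around the requested mean (real complexes span dimers to
      # large assemblies), which also avoids planting a sharp degree mode
      sizes <- pmax(3, stats::rpois(n_complexes, complex_size - 3) + 3)
      if (sum(sizes) > n_proteins) {
        stop("complexes would need more proteins than the proteome holds",
             call. = FALSE)
      }
      members <- sample.int(n_proteins, sum(sizes))
      offsets <- cumsum(c(0, sizes))
      cliques <- lapply(seq_len(n_complexes), function(ci) {
        ids <- members[(offsets[ci] + 1):offsets[ci + 1]]
        t(utils::combn(ids, 2))
      })
      g <- igraph::add_edges(g, t(do.call(rbind, cliques)))
    }
    if (clustering_strength > 0) {
      el <- igraph::as_edgelist(g, names = FALSE)
      close_edge <- which(stats::runif(nrow(el)) < clustering_strength)
      chords <- lapply(close_edge, function(e) {
        u <- el[e, 1]; v <- el[e, 2]
        nb <- setdiff(as.integer(igraph::neighbors(g, u)), v)
        if (length(nb) == 0) return(NULL)
        c(v, nb[sample.int(length(nb), 1)])
      })
      chords <- do.call(rbind, chords)
      if (!is.null(chords)) {
        g <- igraph::add_edges(g, t(chords))
      }
    }
    g
  })
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- canonicalize_pairs(
    tibble::tibble(protein_a = proteins[el[, 1]], protein_b = proteins[el[, 2]]),
    quiet = TRUE
  )
  edges <- dplyr::distinct(dplyr::arrange(edges, .data$protein_a, .data$protein_b))
  structure(
    list(proteins = proteins, true_edges = edges, model = model,
         mean_degree = mean_degree, attachment_power = attachment_power,
         clustering_strength = clustering_strength,
         ontology = NULL, annotations = NULL, seed = seed),
    class = "pg_world"
  )
}

#' @export
print.pg_world <- function(x, ...) {
  cat("<pg_world> ", length(x$proteins), " proteins, ",
      nrow(x$true_edges), " true edges (", x$model, " model)\n", sep = "")
  if (!is.null(x$ontology)) {
    cat("  ontology: ", nrow(x$ontology$terms), " terms; ",
        nrow(x$annotations), " annotations\n", sep = "")
  }
  invisible(x)
}

#' Describe a synthetic predictor
#'
#' A predictor emits Gaussian-null scores; covered true pairs receive an
#' additive mean shift with a given detection rate, emulating an ab-initio
#' method whose score carries signal for genuinely associated pairs.
#'
#' @param name Method label.
#' @param coverage Fraction of all unordered pairs the method scores, in (0, 1].
#' @param null_mean,null_sd Gaussian null score parameters (sd > 0).
#' @param signal_shift Additive mean shift for detected true pairs.
#' @param true_detection_rate Fraction of covered true pairs receiving the
#'   shift, in \[0, 1\].
#' @return A `pg_predictor_profile` list.
#' @export
predictor_profile <- function(name, coverage = 0.5, null_mean = 0, null_sd = 1,
                              signal_shift = 0, true_detection_rate = 1) {
  stopifnot(null_sd > 0, coverage > 0, coverage <= 1,
            true_detection_rate >= 0, true_detection_rate <= 1)
  structure(list(name = name, coverage = coverage, null_mean = null_mean,
                 null_sd = null_sd, signal_shift = signal_shift,
                 true_detection_rate = true_detection_rate),
            class = "pg_predictor_profile")
}

#' Describe a synthetic evidence resource
#'
#' An experimental resource reports a fraction of the true network plus a
#' number of spurious pairs. Resources sharing a `dependency_group` sample from
#' a common pre-draw so their mutual information is elevated, emulating
#' statistically dependent databases.
#'
#' @param name Resource label.
#' @param true_coverage Fraction of true edges reported, in \[0, 1\].
#' @param false_positive_count Number of spurious non-true pairs added.
#' @param dependency_group Group label; defaults to `name` (independent).
#' @return A `pg_resource_profile` list.
#' @export
resource_profile <- function(name, true_coverage = 0.5,
                             false_positive_count = 0,
                             dependency_group = name) {
  stopifnot(true_coverage >= 0, true_coverage <= 1, false_positive_count >= 0)
  structure(list(name = name, true_coverage = true_coverage,
                 false_positive_count = false_positive_count,
                 dependency_group = dependency_group),
            class = "pg_resource_profile")
}

#' Generate one predictor's scored pair dataset
#'
#' Samples `coverage` of the pair universe; non-true pairs draw from
#' `Normal(null_mean, null_sd)`, detected true pairs from
#' `Normal(null_mean + signal_shift, null_sd)`. Higher score means stronger
#' prediction.
#'
#' @param world A [generate_true_network()] world.
#' @param profile A [predictor_profile()].
#' @param seed Integer seed.
#' @return A `pg_predictions` tibble (`protein_a`, `protein_b`, `score`) with
#'   attribute `method`.
#' @export
generate_predictor_scores <- function(world, profile, seed = NULL) {
  stopifnot(inherits(world, "pg_world"), inherits(profile, "pg_predictor_profile"))
  if (length(world$proteins) == 0) stop("empty proteome", call. = FALSE)
  n <- length(world$proteins)
  m <- n_unordered_pairs(n)
  size <- max(1L, round(profile$coverage * m))
  true_keys <- pair_key(world$true_edges$protein_a, world$true_edges$protein_b)
  with_seed(seed, {
    pairs <- sample_pairs(world$proteins, size)
    is_true <- pair_key(pairs$protein_a, pairs$protein_b) %in% true_keys
    detected <- is_true & stats::runif(size) < profile$true_detection_rate
    score <- stats::rnorm(size, profile$null_mean, profile$null_sd) +
      ifelse(detected, profile$signal_shift, 0)
    out <- dplyr::arrange(
      tibble::tibble(protein_a = pairs$protein_a, protein_b = pairs$protein_b,
                     score = score),
      .data$protein_a, .data$protein_b
    )
    structure(out, method = profile$name,
              class = c("pg_predictions", class(out)))
  })
}

#' Generate per-resource evidence datasets
#'
#' Each dataset is a sample of true edges (rate `true_coverage`) plus
#' `false_positive_count` random non-true pairs. Resources sharing a
#' `dependency_group` sample their true edges from a common group-level
#' pre-draw, which elevates their pairwise mutual information.
#'
#' @param world A `pg_world`.
#' @param profiles List of [resource_profile()] objects.
#' @param seed Integer seed.
#' @return Named list of tibbles (`protein_a`, `protein_b`) with attributes
#'   `resource` and `dependency_group`.
#' @export
generate_evidence_datasets <- function(world, profiles, seed = NULL) {
  stopifnot(inherits(world, "pg_world"), length(profiles) >= 1)
  te <- world$true_edges
  groups <- vapply(profiles, `[[`, character(1), "dependency_group")
  covs <- vapply(profiles, `[[`, numeric(1), "true_coverage")
  with_seed(seed, {
    # group pre-draw: the union pool each member samples from
    pool <- lapply(unique(groups), function(g) {
      rate <- min(1, max(covs[groups == g]))
      which(stats::runif(nrow(te)) < rate)
    })
    names(pool) <- unique(groups)
    out <- lapply(profiles, function(pr) {
      g <- pr$dependency_group
      base <- pool[[g]]
      rate <- min(1, max(covs[groups == g]))
      keep_p <- if (rate > 0) pr$true_coverage / rate else 0
      keep <- base[stats::runif(length(base)) < keep_p]
      edges <- te[keep, , drop = FALSE]
      if (pr$false_positive_count > 0) {
        fp <- sample_pairs(world$proteins, pr$false_positive_count,
                           exclude_keys = pair_key(te$protein_a, te$protein_b))
        edges <- dplyr::bind_rows(edges, fp)
      }
      edges <- dplyr::distinct(dplyr::arrange(edges, .data$protein_a, .data$protein_b))
      structure(edges, resource = pr$name, dependency_group = g)
    })
    names(out) <- vapply(profiles, `[[`, character(1), "name")
    out
  })
}

#' Generate a toy ontology and biased annotations
#'
#' Builds a rooted `branching`-ary tree of `n_terms` terms (breadth-first
#' filling, so `branching = 2, n_terms = 7` is a perfect binary tree of depth
#' 2) and annotates every protein with `n_annotations` uniformly drawn terms.
#' With `bias > 0`, each true edge additionally co-annotates both of its
#' endpoints with one shared non-root term with that probability, planting
#' Resnik-similarity signal on true pairs (their most informative common
#' ancestor is then at least that shared term).
#'
#' @param world A `pg_world`.
#' @param n_terms Number of ontology terms (>= 3).
#' @param branching Children per internal term.
#' @param n_annotations Annotation terms per protein.
#' @param bias Probability, per true edge, of co-annotating its two endpoints
#'   with a shared term.
#' @param seed Integer seed.
#' @return The world with `ontology` (a `pg_ontology`) and `annotations`
#'   (tibble `protein`, `term`) filled in.
#' @export
generate_ontology <- function(world, n_terms, branching = 2,
                              n_annotations = 2, bias = 0, seed = NULL) {
  stopifnot(inherits(world, "pg_world"), n_terms >= 3, branching >= 1,
            n_annotations >= 1, bias >= 0, bias <= 1)
  ids <- sprintf("T%04d", seq_len(n_terms))
  parent_of <- function(i) ids[floor((i - 2) / branching) + 1]
  edges <- tibble::tibble(
    child = ids[-1],
    parent = vapply(2:n_terms, parent_of, character(1))
  )
  onto <- new_ontology(tibble::tibble(id = ids, name = paste("term", ids)), edges)
  world$ontology <- onto
  world$annotations <- with_seed(seed, {
    base <- tibble::tibble(
      protein = rep(world$proteins, each = n_annotations),
      term = ids[sample.int(n_terms, length(world$proteins) * n_annotations,
                            replace = TRUE)]
    )
    te <- world$true_edges
    non_root <- ids[-1]
    planted <- if (bias > 0 && nrow(te) > 0 && length(non_root) > 0) {
      co <- which(stats::runif(nrow(te)) < bias)
      shared <- non_root[sample.int(length(non_root), length(co),
                                    replace = TRUE)]
      tibble::tibble(
        protein = c(te$protein_a[co], te$protein_b[co]),
        term = c(shared, shared)
      )
    } else {
      base[0, ]
    }
    dplyr::arrange(dplyr::distinct(dplyr::bind_rows(base, planted)),
                   .data$protein, .data$term)
  })
  world
}

#' Write the synthetic world's datasets to a directory
#'
#' Prediction and evidence datasets are written as 3- and 2-column TSV, the
#' ontology as minimal OBO (id, name, is_a) and annotations as 2-column TSV.
#'
#' @param world A `pg_world` (with ontology if generated).
#' @param predictions Named list of prediction tibbles.
#' @param evidence Named list of evidence tibbles.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, predictions = list(), evidence = list(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_pair_tsv(world$true_edges, file.path(dir, "true_edges.tsv"))
  for (nm in names(predictions)) {
    write_pair_tsv(predictions[[nm]], file.path(dir, paste0("pred_", nm, ".tsv")))
  }
  for (nm in names(evidence)) {
    write_pair_tsv(evidence[[nm]], file.path(dir, paste0("evidence_", nm, ".tsv")))
  }
  if (!is.null(world$ontology)) {
    write_obo(world$ontology, file.path(dir, "ontology.obo"))
    readr::write_tsv(world$annotations, file.path(dir, "annotations.tsv"))
  }
  invisible(dir)
}
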