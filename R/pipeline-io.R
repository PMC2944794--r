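#' Read an edge-list TSV of protein pairs
#'
#' Accepts 2- or 3-column TSV (`protein_a  protein_b  [score]`), header
#' optional (detected from the first line). Pairs are canonicalized; self-pairs
#' are dropped with a warning; duplicate pairs with identical weights are
#' deduplicated, conflicting weights are an error naming the offending lines.
#'
#' @param path File path.
#' @param expect_weight Require a third column (`TRUE`), forbid it (`FALSE`),
#'   or accept either (`NA`, default).
#' @param weight_name Name given to the third column (default `"score"`).
#' @return A canonical, deduplicated pair tibble.
#' @export
read_pair_tsv <- function(path, expect_weight = NA, weight_name = "score") {
  first <- readLines(path, n = 1)
  if (length(first) == 0) stop("empty file: ", path, call. = FALSE)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  has_weight <- length(fields) >= 3
  if (isTRUE(expect_weight) && !has_weight) {
    stop(path, ": expected a weight column", call. = FALSE)
  }
  if (isFALSE(expect_weight) && has_weight) {
    stop(path, ": unexpected weight column", call. = FALSE)
  }
  has_header <- has_weight && is.na(suppressWarnings(as.numeric(fields[3]))) ||
    (!has_weight && any(grepl("^protein", fields, ignore.case = TRUE)))
  cols <- if (has_weight) {
    c("protein_a", "protein_b", weight_name)
  } else {
    c("protein_a", "protein_b")
  }
  types <- if (has_weight) "ccd" else "cc"
  x <- readr::read_tsv(path, col_names = cols, col_types = types,
                       skip = as.integer(has_header), progress = FALSE)
  bad <- if (has_weight) which(!is.finite(x[[weight_name]])) else integer(0)
  if (length(bad) > 0) {
    stop(path, ": malformed row(s) at line ",
         paste(bad + has_header, collapse = ", "), call. = FALSE)
  }
  x <- canonicalize_pairs(x)
  keys <- pair_key(x$protein_a, x$protein_b)
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)]
    rows <- which(keys %in% dup)
    if (has_weight) {
      conflicting <- any(stats::ave(x[[weight_name]], keys,
                                    FUN = function(v) length(unique(v)))[rows] > 1)
      if (conflicting) {
        stop(path, ": duplicate pairs with conflicting weights at lines ",
             paste(rows + has_header, collapse = ", "), call. = FALSE)
      }
    }
    x <- x[!duplicated(keys), ]
  }
  x
}

#' Write a pair tibble as TSV
#' @param x Pair tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Read a minimal OBO ontology (id, name, is_a)
#'
#' Parses only `[Term]` stanzas and their `id`, `name` and `is_a` tags; every
#' other tag and stanza type is ignored.
#'
#' @param path OBO file path.
#' @return A `pg_ontology`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0) stop("no [Term] stanzas in ", path, call. = FALSE)
  bounds <- c(term_starts, length(lines) + 1)
  terms <- list()
  edges <- list()
  for (s in seq_along(term_starts)) {
    block <- lines[(bounds[s] + 1):(bounds[s + 1] - 1)]
    block <- block[!grepl("^\\[", block)]
    tag <- function(name) {
      v <- sub(paste0("^", name, ":\\s*"), "",
               grep(paste0("^", name, ":"), block, value = TRUE))
      sub("\\s*!.*$", "", v)
    }
    id <- tag("id")
    if (length(id) == 0) next
    nm <- tag("name")
    terms[[s]] <- tibble::tibble(id = id[1],
                                 name = if (length(nm)) nm[1] else id[1])
    isa <- tag("is_a")
    if (length(isa) > 0) {
      edges[[s]] <- tibble::tibble(child = id[1], parent = isa)
    }
  }
  new_ontology(dplyr::bind_rows(terms),
               dplyr::bind_rows(edges) %||%
                 tibble::tibble(child = character(), parent = character()))
}

#' Write a minimal OBO ontology
#' @param ontology A `pg_ontology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  parents <- split(ontology$edges$parent, ontology$edges$child)
  stanzas <- vapply(seq_len(nrow(ontology$terms)), function(i) {
    id <- ontology$terms$id[i]
    lines <- c("[Term]", paste0("id: ", id),
               paste0("name: ", ontology$terms$name[i]),
               if (!is.null(parents[[id]])) paste0("is_a: ", parents[[id]]))
    paste(lines, collapse = "\n")
  }, character(1))
  writeLines(c("format-version: 1.2", "", paste(stanzas, collapse = "\n\n")),
             path)
  invisible(path)
}

#' Read a 2-column annotation TSV (protein, term)
#' @param path File path.
#' @return Tibble `protein`, `term`.
#' @export
read_annotations <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("protein", first, ignore.case = TRUE)
  readr::read_tsv(path, col_names = c("protein", "term"), col_types = "cc",
                  skip = as.integer(has_header), progress = FALSE)
}

#' Pipeline configuration
#'
#' Bundles all stage parameters for [run_pipeline()]. Defaults give a
#' desk-scale synthetic study: a 600-protein preferential-attachment world,
#' four predictors of which two carry signal, and six evidence resources of
#' which two are mutually dependent.
#'
#' @param n_proteins,mean_degree,attachment_power,clustering_strength
#'   True-network parameters; the default plants a heavy-tailed, clustered
#'   truth as observed in real interactomes.
#' @param predictors List of [predictor_profile()]s.
#' @param resources List of [resource_profile()]s.
#' @param ontology_terms,ontology_branching,annotation_bias Ontology generator
#'   parameters.
#' @param goss_threshold Semantic-similarity cutoff for ontology-derived
#'   evidence (default 4.0 nats).
#' @param integration `"fisher"` or `"simple"`.
#' @param optimize_weights Run the annealing weight search (default TRUE).
#' @param pg_cutoffs PG p-value cutoffs to build (first = the analysed one).
#' @param kg_min_evidence KG evidence cutoff.
#' @param n_random Random models for precision/recall.
#' @param baseline_iterations Randomization iterations for intersections.
#' @param seed Mandatory global seed; stage seeds are derived from it.
#' @param out_dir Optional output directory for TSV/OBO artifacts.
#' @return A `pg_config` list.
#' @export
pipeline_config <- function(n_proteins = 600, mean_degree = 6,
                            attachment_power = 1, clustering_strength = 0.3,
                            predictors = default_predictors(),
                            resources = default_resources(),
                            ontology_terms = 60, ontology_branching = 3,
                            annotation_bias = 0.7, goss_threshold = 4.0,
                            integration = "fisher", optimize_weights = TRUE,
                            pg_cutoffs = c(0.01, 0.05, 0.2),
                            kg_min_evidence = 2, n_random = 100,
                            baseline_iterations = 200, seed = NULL,
                            out_dir = NULL) {
  if (is.null(seed)) {
    stop("a seed is mandatory: every stochastic stage derives its seed from it",
         call. = FALSE)
  }
  cfg <- as.list(environment())
  structure(cfg, class = "pg_config")
}

#' Default synthetic predictor panel
#' @return List of four [predictor_profile()]s, two informative and two noise.
#' @export
default_predictors <- function() {
  list(
    predictor_profile("coexpr",  coverage = 0.70, signal_shift = 1.2),
    predictor_profile("homology", coverage = 0.60, signal_shift = 1.5),
    predictor_profile("domfuse_a", coverage = 0.50, signal_shift = 0),
    predictor_profile("domfuse_b", coverage = 0.40, signal_shift = 0)
  )
}

#' Default synthetic evidence panel
#' @return List of six [resource_profile()]s; the two ontology-style resources
#'   share a dependency group.
#' @export
default_resources <- function() {
  list(
    resource_profile("intdb_1", true_coverage = 0.25, false_positive_count = 60),
    resource_profile("intdb_2", true_coverage = 0.20, false_positive_count = 60),
    resource_profile("intdb_3", true_coverage = 0.15, false_positive_count = 40),
    resource_profile("pathway_1", true_coverage = 0.30, false_positive_count = 80),
    resource_profile("onto_a", true_coverage = 0.35, false_positive_count = 100,
                     dependency_group = "onto"),
    resource_profile("onto_b", true_coverage = 0.30, false_positive_count = 100,
                     dependency_group = "onto")
  )
}

#' Run the full synthetic-world pipeline
#'
#' Chains every stage: world simulation, predictor score generation and
#' normalization, weight optimization and integration, gold-standard
#' benchmarking, PG/KG construction, topology characterization, intersection
#' and dark-matter statistics, dark-hub ranking with functional enrichment,
#' and second-order prediction with KG validation. Re-running with the same
#' configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A `pg_pipeline_result` list with all stage artifacts plus the
#'   config and its hash.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pg_config"))
  seeds <- derive_seeds(config$seed, 10)
  world <- generate_true_network(config$n_proteins, config$mean_degree,
                                 model = "pa",
                                 attachment_power = config$attachment_power,
                                 clustering_strength = config$clustering_strength,
                                 seed = seeds[1])
  world <- generate_ontology(world, n_terms = config$ontology_terms,
                             branching = config$ontology_branching,
                             n_annotations = 2, bias = config$annotation_bias,
                             seed = seeds[2])
  profs <- stats::setNames(config$predictors,
                           vapply(config$predictors, `[[`, character(1), "name"))
  predictions <- purrr::imap(profs, function(p, nm) {
    generate_predictor_scores(world, p,
                              seed = seeds[3] + match(nm, names(profs)))
  })
  normalized <- purrr::map(predictions, normalize_scores)
  mi <- mutual_information_matrix(normalized)
  weights <- if (isTRUE(config$optimize_weights) && length(normalized) >= 2) {
    optimize_weights(normalized, seed = seeds[4])
  }
  integrated <- integrate_predictions(normalized, method = config$integration,
                                      weights = weights)
  evidence <- generate_evidence_datasets(world, config$resources,
                                         seed = seeds[5])
  gossr <- build_semantic_pairset(world$proteins, world$annotations,
                                  world$ontology,
                                  threshold = config$goss_threshold)
  bench <- precision_recall(
    stats::setNames(integrated[, c("protein_a", "protein_b",
                                   "integrated_pvalue")],
                    c("protein_a", "protein_b", "p_value")),
    gold = world$true_edges, node_universe = world$proteins,
    n_random = config$n_random, seed = seeds[6]
  )
  pg_full <- build_pg(integrated, 1)
  pgs <- purrr::map(config$pg_cutoffs, ~ build_pg(integrated, .x))
  names(pgs) <- paste0("PG_", config$pg_cutoffs)
  kg_full <- build_kg(evidence, min_evidence = 1)
  kg <- build_kg(evidence, min_evidence = config$kg_min_evidence)
  pg <- pgs[[1]]
  topo <- purrr::map(pgs, topology_summary)
  inter <- intersect_with_baselines(pg_full, kg_full,
                                    pg_cutoff = config$pg_cutoffs[1],
                                    kg_min_evidence = config$kg_min_evidence,
                                    null = "weights",
                                    iterations = config$baseline_iterations,
                                    seed = seeds[7])
  hubs <- rank_dark_hubs(pg, kg_full)
  enr <- ranked_enrichment(hubs$protein, world$annotations, world$ontology,
                           significance_threshold = Inf)
  so <- second_order_scores(pg, congruence = length(network_nodes(pg)) <= 5000)
  so_curve <- if (nrow(so) > 0 && nrow(kg) > 0) {
    tryCatch(
      validate_second_order(so, evidence, n_random = config$n_random,
                            seed = seeds[8]),
      error = function(e) NULL
    )
  }
  result <- structure(
    list(world = world, predictions = normalized, mutual_information = mi,
         weights = weights, integrated = integrated, evidence = evidence,
         gossr = gossr, benchmark = bench, pg = pgs, pg_full = pg_full,
         kg = kg, kg_full = kg_full, topology = topo, intersection = inter,
         dark_node_pct = dark_node_fraction(pg, kg_full), dark_hubs = hubs,
         enrichment = enr, second_order = so, second_order_curve = so_curve,
         config = config, config_hash = rlang::hash(unclass(config))),
    class = "pg_pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

# Deterministic per-stage seeds below 2^31.
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 1103515245 + 12345 * seq_len(n)) %% 2147483647
}

write_pipeline_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stamp <- c(paste0("# config_hash: ", result$config_hash),
             paste0("# seed: ", result$config$seed))
  writeLines(stamp, file.path(dir, "provenance.txt"))
  write_world(result$world, result$predictions, result$evidence, dir)
  write_pair_tsv(result$integrated, file.path(dir, "integrated.tsv"))
  for (nm in names(result$pg)) {
    write_pair_tsv(result$pg[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  write_pair_tsv(result$kg, file.path(dir, "KG.tsv"))
  readr::write_tsv(result$dark_hubs, file.path(dir, "dark_hubs.tsv"))
  readr::write_tsv(result$second_order, file.path(dir, "second_order.tsv"))
  invisible(dir)
}

#' @export
print.pg_pipeline_result <- function(x, ...) {
  cat("<pg_pipeline_result> seed ", x$config$seed, ", hash ",
      x$config_hash, "\n", sep = "")
  cat("  world: ", length(x$world$proteins), " proteins / ",
      nrow(x$world$true_edges), " true edges\n", sep = "")
  cat("  PG networks: ", paste(names(x$pg), collapse = ", "), "\n", sep = "")
  cat("  %PGe = ", round(x$intersection$pct_pg_backed, 2),
      ", dark nodes = ", round(x$dark_node_pct, 1), "%\n", sep = "")
  invisible(x)
}
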