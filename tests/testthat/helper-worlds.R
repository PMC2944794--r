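# Shared synthetic-study builder with session-level caching, so that several
# test files can reuse the same desk-scale world without regenerating it.

.world_cache <- new.env(parent = emptyenv())

# Standard study conditions: four predictors, two informative, six resources
# (two sharing a dependency group), preferential-attachment truth.
study_predictors <- function(informative = 2, k = 4) {
  # high overlapping coverage, as for proteome-wide prediction runs; graded
  # signal on every covered true pair (failures to assess a pair are coverage)
  profs <- list(
    predictor_profile("m1", coverage = 0.70, signal_shift = 1.2),
    predictor_profile("m2", coverage = 0.60, signal_shift = 1.5),
    predictor_profile("m3", coverage = 0.50, signal_shift = 0),
    predictor_profile("m4", coverage = 0.40, signal_shift = 0)
  )[seq_len(k)]
  if (informative < 1) profs[[1]]$signal_shift <- 0
  if (informative < 2) profs[[2]]$signal_shift <- 0
  if (informative > 2) profs[[3]]$signal_shift <- 1.0
  profs
}

build_study <- function(n = 500, seed = 1, informative = 2,
                        mean_degree = 6, optimize = FALSE) {
  key <- paste(n, seed, informative, mean_degree, optimize, sep = "_")
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  world <- generate_true_network(n, mean_degree = mean_degree,
                                 clustering_strength = 0.3, seed = seed)
  world <- generate_ontology(world, n_terms = 40, branching = 3,
                             n_annotations = 2, bias = 0.7, seed = seed + 1)
  profs <- study_predictors(informative)
  names(profs) <- vapply(profs, `[[`, character(1), "name")
  normalized <- lapply(seq_along(profs), function(i) {
    normalize_scores(generate_predictor_scores(world, profs[[i]],
                                               seed = seed + 10 + i))
  })
  names(normalized) <- names(profs)
  weights <- if (optimize) {
    optimize_weights(normalized, n_steps = 60, sample_pairs = 50000,
                     seed = seed + 20)
  }
  integrated <- integrate_predictions(normalized, weights = weights)
  evidence <- generate_evidence_datasets(world, default_resources(),
                                         seed = seed + 30)
  res <- list(world = world, normalized = normalized, weights = weights,
              integrated = integrated, evidence = evidence)
  .world_cache[[key]] <- res
  res
}

integrated_as_predictions <- function(integrated) {
  stats::setNames(
    integrated[, c("protein_a", "protein_b", "integrated_pvalue")],
    c("protein_a", "protein_b", "p_value")
  )
}

# High-precision operating point: near-complete coverage and strong graded
# signal, so the tight-cutoff PG reaches the reliability regime at which the
# topology claims are made (precision >= 0.8 with most of the truth
# recovered). The world is passed in because the two topology sub-claims are
# planted separately (complex-rich for clustering, attachment-only for the
# degree tail).
strong_study <- function(world, seed) {
  profs <- list(
    predictor_profile("m1", coverage = 0.90, signal_shift = 4.0),
    predictor_profile("m2", coverage = 0.80, signal_shift = 4.5),
    predictor_profile("m3", coverage = 0.50, signal_shift = 0),
    predictor_profile("m4", coverage = 0.40, signal_shift = 0)
  )
  np <- lapply(seq_along(profs), function(i) {
    normalize_scores(generate_predictor_scores(world, profs[[i]],
                                               seed = seed + i))
  })
  names(np) <- vapply(profs, `[[`, character(1), "name")
  wt <- optimize_weights(np, n_steps = 60, sample_pairs = 50000,
                         seed = seed + 10)
  list(world = world, normalized = np, weights = wt,
       integrated = integrate_predictions(np, weights = wt))
}

# Prediction power of every single method, weighted Fisher and simple
# integration, evaluated over a common recall window (the smallest method's
# total hit count) so list length does not bias the comparison.
compare_powers <- function(st, n_random = 20, seed = 1, max_points = 1500) {
  gold <- st$world$true_edges
  uni <- st$world$proteins
  curves <- c(
    lapply(st$normalized, function(d) {
      precision_recall(d, gold, node_universe = uni, n_random = n_random,
                       seed = seed, max_points = max_points)
    }),
    list(
      fisher = precision_recall(integrated_as_predictions(st$integrated),
                                gold, node_universe = uni,
                                n_random = n_random, seed = seed,
                                max_points = max_points),
      simple = precision_recall(
        integrated_as_predictions(
          integrate_predictions(st$normalized, method = "simple")
        ),
        gold, node_universe = uni, n_random = n_random, seed = seed,
        max_points = max_points
      )
    )
  )
  window <- min(vapply(curves, function(cc) max(cc$recall), numeric(1)))
  vapply(curves, prediction_power, numeric(1), max_recall = window)
}
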