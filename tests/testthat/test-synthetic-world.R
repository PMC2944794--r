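test_that("true-network generation is seeded, simple and canonical", {
  w1 <- generate_true_network(100, mean_degree = 2, seed = 1)
  w2 <- generate_true_network(100, mean_degree = 2, seed = 1)
  expect_identical(w1$true_edges, w2$true_edges)
  expect_false(identical(
    w1$true_edges, generate_true_network(100, mean_degree = 2, seed = 2)$true_edges
  ))

  tiny <- generate_true_network(10, mean_degree = 0.2, seed = 3)
  expect_lte(nrow(tiny$true_edges), 3)
  expect_true(all(tiny$true_edges$protein_a != tiny$true_edges$protein_b))
  expect_true(all(tiny$true_edges$protein_a < tiny$true_edges$protein_b))
  expect_false(anyDuplicated(pair_key(tiny$true_edges$protein_a,
                                      tiny$true_edges$protein_b)) > 0)

  expect_error(generate_true_network(5), "n_proteins")
  expect_error(generate_true_network(100, mean_degree = -1), "mean_degree")
})

test_that("preferential attachment plants a heavy tail with the expected exponent", {
  w <- generate_true_network(2000, mean_degree = 6, seed = 7)
  net <- as_net(w$true_edges)
  fit <- fit_power_law(degree_histogram(net))
  # reference exponent from large-sample runs of this same generator
  # (n = 20000 log-log fits land near 2.3)
  expect_gt(fit$gamma, 2.33 - 0.5)
  expect_lt(fit$gamma, 2.33 + 0.5)
  expect_lt(fit$r, -0.8)  # strong log-log linearity, negative slope
})

test_that("predictor scores follow the stated null/signal mixture", {
  w <- generate_true_network(50, mean_degree = 2, seed = 1)
  full <- generate_predictor_scores(
    w, predictor_profile("m", coverage = 1), seed = 2
  )
  expect_identical(nrow(full), as.integer(50 * 49 / 2))
  expect_true(all(full$protein_a < full$protein_b))

  # pure-null sampler calibration at large n
  w2 <- generate_true_network(500, mean_degree = 0.1, seed = 3)
  w2$true_edges <- w2$true_edges[0, ]  # no true pairs at all
  big <- generate_predictor_scores(
    w2, predictor_profile("m", coverage = 0.9, null_mean = 0, null_sd = 1),
    seed = 4
  )
  expect_gt(nrow(big), 1e5)
  expect_lt(abs(mean(big$score)), 0.02)
  expect_lt(abs(sd(big$score) - 1), 0.02)
})

test_that("signal shift separates true from null pairs; zero shift does not", {
  w <- generate_true_network(300, mean_degree = 10, seed = 5)
  true_keys <- pair_key(w$true_edges$protein_a, w$true_edges$protein_b)

  flat <- generate_predictor_scores(
    w, predictor_profile("m", coverage = 0.5, signal_shift = 0), seed = 6
  )
  is_true <- pair_key(flat$protein_a, flat$protein_b) %in% true_keys
  expect_gt(ks.test(flat$score[is_true], flat$score[!is_true])$p.value, 0.01)

  shifted <- generate_predictor_scores(
    w, predictor_profile("m", coverage = 0.5, signal_shift = 2), seed = 6
  )
  is_true_s <- pair_key(shifted$protein_a, shifted$protein_b) %in% true_keys
  # AUC > 0.5: one-sided rank test of true vs null scores
  wt <- wilcox.test(shifted$score[is_true_s], shifted$score[!is_true_s],
                    alternative = "greater")
  expect_lt(wt$p.value, 1e-6)
})

test_that("evidence datasets sample the truth with resource-specific noise", {
  w <- generate_true_network(100, mean_degree = 4, seed = 1)
  all_of_it <- generate_evidence_datasets(
    w, list(resource_profile("r", true_coverage = 1)), seed = 2
  )[[1]]
  expect_equal(tibble::as_tibble(all_of_it)[, 1:2], w$true_edges,
               ignore_attr = TRUE)

  only_noise <- generate_evidence_datasets(
    w, list(resource_profile("r", true_coverage = 0,
                             false_positive_count = 10)), seed = 3
  )[[1]]
  expect_identical(nrow(only_noise), 10L)
  true_keys <- pair_key(w$true_edges$protein_a, w$true_edges$protein_b)
  expect_false(any(pair_key(only_noise$protein_a, only_noise$protein_b)
                   %in% true_keys))
})

test_that("dependency groups elevate mutual information between resources", {
  w <- generate_true_network(200, mean_degree = 10, seed = 9)
  ev <- generate_evidence_datasets(w, list(
    resource_profile("g1", true_coverage = 0.5, dependency_group = "shared"),
    resource_profile("g2", true_coverage = 0.5, dependency_group = "shared"),
    resource_profile("i1", true_coverage = 0.5),
    resource_profile("i2", true_coverage = 0.5)
  ), seed = 10)
  member <- function(d) {
    pair_key(w$true_edges$protein_a, w$true_edges$protein_b) %in%
      pair_key(d$protein_a, d$protein_b)
  }
  mi_grouped <- brute_binary_mi(member(ev$g1), member(ev$g2))
  mi_indep <- brute_binary_mi(member(ev$i1), member(ev$i2))
  expect_gt(mi_grouped, mi_indep)
  expect_gt(mi_grouped, 0.1)
  expect_lt(mi_indep, 0.05)
})

test_that("toy ontology is the expected tree and bias plants semantic signal", {
  w <- generate_true_network(10, mean_degree = 1, seed = 1)
  w <- generate_ontology(w, n_terms = 7, branching = 2, seed = 2)
  onto <- w$ontology
  expect_identical(onto$roots, "T0001")
  expect_identical(
    onto$edges$parent,
    c("T0001", "T0001", "T0002", "T0002", "T0003", "T0003")
  )

  score_gap <- function(bias, seed) {
    wb <- generate_true_network(150, mean_degree = 4, seed = seed)
    wb <- generate_ontology(wb, n_terms = 40, branching = 3,
                            n_annotations = 2, bias = bias, seed = seed + 1)
    te <- wb$true_edges[sample.int(nrow(wb$true_edges), 200, replace = TRUE), ]
    rnd <- sample_pairs(wb$proteins, 300)
    m <- resnik_matrix(wb$proteins, wb$annotations, wb$ontology)
    get <- function(p) {
      v <- m[cbind(p$protein_a, p$protein_b)]
      v[is.na(v)] <- 0
      v
    }
    c(true = mean(get(te)), random = mean(get(rnd)))
  }
  set.seed(42)
  biased <- score_gap(0.9, 11)
  expect_gt(biased["true"], biased["random"] * 1.2)
  flat <- score_gap(0, 13)
  expect_lt(abs(flat["true"] - flat["random"]), 0.5)
})

test_that("pair sampling enumerates the universe without self-pairs or duplicates", {
  prots <- sprintf("Q%02d", 1:13)
  set.seed(1)
  all_pairs <- sample_pairs(prots, choose(13, 2))
  expect_equal(nrow(all_pairs), choose(13, 2))
  keys <- pair_key(all_pairs$protein_a, all_pairs$protein_b)
  ref <- utils::combn(sort(prots), 2)
  expect_setequal(keys, pair_key(ref[1, ], ref[2, ]))
  expect_true(all(all_pairs$protein_a < all_pairs$protein_b))

  some <- sample_pairs(prots, 20, exclude_keys = keys[1:50])
  expect_false(any(pair_key(some$protein_a, some$protein_b) %in% keys[1:50]))
  expect_equal(nrow(some), 20)
})

test_that("a fixed seed fixes every generated artifact", {
  gen <- function() {
    w <- generate_true_network(80, mean_degree = 3, seed = 5)
    w <- generate_ontology(w, n_terms = 13, branching = 3, bias = 0.5, seed = 6)
    p <- generate_predictor_scores(w, predictor_profile("m", coverage = 0.5),
                                   seed = 7)
    e <- generate_evidence_datasets(w, list(resource_profile("r", 0.5, 5)),
                                    seed = 8)
    list(w$true_edges, w$annotations, tibble::as_tibble(p),
         tibble::as_tibble(e[[1]]))
  }
  expect_identical(gen(), gen())
})
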