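test_that("intersection statistics cover the identical and disjoint extremes", {
  net <- as_net(pairs_tbl(c("A", "A", "B"), c("B", "C", "C")))
  self <- network_intersection(net, net)
  expect_equal(self$pct_pg_backed, 100)
  expect_equal(self$density, 3 / 3)

  other <- as_net(pairs_tbl(c("X", "Y"), c("Y", "Z")))
  none <- network_intersection(net, other)
  expect_equal(none$n_edges_shared, 0)
  expect_equal(none$density, 0)
  expect_equal(none$pct_pg_backed, 0)
})

test_that("overlap is significant when PG and KG share the truth, not otherwise", {
  st <- build_study(n = 300, seed = 31)
  pg_full <- build_pg(st$integrated, 1)
  kg_full <- build_kg(st$evidence, min_evidence = 1)
  rep <- intersect_with_baselines(pg_full, kg_full, pg_cutoff = 0.02,
                                  kg_min_evidence = 2, null = "weights",
                                  iterations = 150, seed = 1)
  b <- rep$baselines$weights
  z <- (rep$pct_pg_backed - b$pct_pg_backed_mean) /
    max(b$pct_pg_backed_sd, 1e-9)
  expect_gt(z, 3)
  expect_gt(rep$enrichment_ratios$weights, 1)

  # PG built from pure-noise predictors is not enriched over its null
  noise <- build_study(n = 300, seed = 32, informative = 0)
  pg_noise <- build_pg(noise$integrated, 1)
  rep0 <- intersect_with_baselines(pg_noise, kg_full, pg_cutoff = 0.02,
                                   kg_min_evidence = 2, null = "weights",
                                   iterations = 150, seed = 2)
  b0 <- rep0$baselines$weights
  z0 <- (rep0$pct_pg_backed - b0$pct_pg_backed_mean) /
    max(b0$pct_pg_backed_sd, 1e-9)
  expect_lt(z0, 3)
})

test_that("dark-node fraction counts PG nodes unseen by the KG", {
  pg <- as_net(pairs_tbl(c("A", "C", "E"), c("B", "D", "F")))
  kg_all <- as_net(pairs_tbl(c("A", "C", "E", "A"), c("B", "D", "F", "F")))
  expect_equal(dark_node_fraction(pg, kg_all), 0)
  kg_half <- as_net(pairs_tbl("A", "B"))
  expect_equal(dark_node_fraction(pg, kg_half), 100 * 4 / 6)
})

test_that("dark-hub ranking applies the degree-enrichment formula with id tie-breaks", {
  pg <- as_net(dplyr::bind_rows(
    pairs_tbl(rep("HUB", 10), sprintf("N%02d", 1:10)),
    pairs_tbl("X", "Y")
  ))
  kg <- as_net(pairs_tbl(c("HUB", "HUB", "HUB", "HUB", "X"),
                         c("N01", "N02", "N03", "N04", "Y")))
  hubs <- rank_dark_hubs(pg, kg)
  hub_row <- hubs[hubs$protein == "HUB", ]
  expect_equal(hub_row$pg_ki_er, (10 - 4) / (4 + 1))  # 1.2
  x_row <- hubs[hubs$protein == "X", ]
  expect_equal(x_row$pg_ki_er, 0)  # equal degree in both networks
  leaf <- hubs[hubs$protein == "N05", ]
  expect_equal(leaf$pg_ki_er, 1)  # degree 1 in PG, absent from KG
  expect_equal(hubs$rank, seq_len(nrow(hubs)))
  ties <- hubs[hubs$pg_ki_er == 1, ]
  expect_identical(ties$protein, sort(ties$protein))
})

test_that("planted evidence-hidden hubs rise to the top of the ranking", {
  mean_ranks <- vapply(1:4, function(s) {
    st <- build_study(n = 300, seed = 600 + s)
    deg <- sort(table(c(st$world$true_edges$protein_a,
                        st$world$true_edges$protein_b)), decreasing = TRUE)
    hidden <- names(deg)[1:5]
    censored <- lapply(st$evidence, function(d) {
      keep <- !(d$protein_a %in% hidden | d$protein_b %in% hidden)
      out <- d[keep, ]
      attr(out, "dependency_group") <- attr(d, "dependency_group")
      out
    })
    pg <- build_pg(st$integrated, 0.02)
    kg <- build_kg(censored, min_evidence = 1)
    hubs <- rank_dark_hubs(pg, kg)
    found <- hubs$rank[hubs$protein %in% hidden]
    mean(found) / nrow(hubs)
  }, numeric(1))
  expect_lt(mean(mean_ranks), 0.1)  # top decile on average
})

test_that("ranked enrichment reproduces the fixed-cutoff arithmetic", {
  # one rare term annotating 124 of 12769 ranked proteins, 39 in the top 982
  n_total <- 12769; b_total <- 124; top <- 982; hits <- 39
  prots <- sprintf("G%05d", seq_len(n_total))
  annotated <- c(sample(prots[1:top], hits), sample(prots[(top + 1):n_total],
                                                    b_total - hits))
  onto <- new_ontology(
    tibble::tibble(id = c("root", "t1"), name = c("root", "t1")),
    tibble::tibble(child = "t1", parent = "root")
  )
  ann <- tibble::tibble(protein = annotated, term = "t1")
  res <- ranked_enrichment(prots, ann, onto, top_n = top,
                           significance_threshold = Inf)
  row <- res[res$term == "t1", ]
  expect_equal(row$N, n_total)
  expect_equal(row$B, b_total)
  expect_equal(row$n, top)
  expect_equal(row$b, hits)
  expect_equal(row$enrichment, (hits / top) / (b_total / n_total))
  expect_equal(round(row$enrichment), 4)
  expect_equal(row$p_value,
               phyper(hits - 1, b_total, n_total - b_total, top,
                      lower.tail = FALSE))
})

test_that("flexible-cutoff enrichment finds the concentrated prefix", {
  prots <- sprintf("G%03d", 1:200)
  onto <- new_ontology(
    tibble::tibble(id = c("root", "t1"), name = c("root", "t1")),
    tibble::tibble(child = "t1", parent = "root")
  )
  ann <- tibble::tibble(protein = prots[1:20], term = "t1")  # all at the top
  res <- ranked_enrichment(prots, ann, onto, top_n = NULL,
                           significance_threshold = Inf)
  row <- res[res$term == "t1", ]
  expect_equal(row$n, 20)
  expect_equal(row$b, 20)
  expect_lt(row$p_value, 1e-20)
  # E = 1 when the top is a proportional sample
  expect_equal(enrichment_ratio(100, 10, 50, 5), 1)
  expect_equal(enrichment_ratio(100, 10, 10, 0), 0)
})

test_that("enrichment tail probabilities agree with exhaustive enumeration", {
  onto <- new_ontology(
    tibble::tibble(id = c("root", "t1"), name = c("root", "t1")),
    tibble::tibble(child = "t1", parent = "root")
  )
  set.seed(1)
  for (i in 1:15) {
    N <- sample(8:30, 1)
    B <- sample(2:(N - 2), 1)
    top <- sample(2:(N - 1), 1)
    prots <- sprintf("G%02d", seq_len(N))
    ann <- tibble::tibble(protein = sample(prots, B), term = "t1")
    res <- ranked_enrichment(prots, ann, onto, top_n = top,
                             significance_threshold = Inf)
    row <- res[res$term == "t1", ]
    expect_equal(row$p_value, brute_hyper_tail(row$b, B, N - B, top),
                 tolerance = 1e-10)
  }
})
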