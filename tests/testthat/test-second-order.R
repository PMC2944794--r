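test_that("candidate pairs apply the one-third sharing rule inclusively", {
  # L1 and L2 both see exactly {H}: identical neighbor sets, fraction 1
  star <- as_net(pairs_tbl(rep("H", 3), c("L1", "L2", "L3")))
  cands <- candidate_pairs(star)
  expect_true("L1" %in% cands$protein_a | "L1" %in% cands$protein_b)
  expect_equal(nrow(cands), 3)  # every leaf pair shares the hub

  # b1 = 1, b2 = 2: fraction exactly 1/3, kept by the >= boundary
  net <- as_net(pairs_tbl(c("A", "A", "X", "B"), c("S", "P", "B", "Q")))
  # A's neighbors {S, P}; B's {X, Q}: disjoint, so the pair is excluded
  cands2 <- candidate_pairs(net)
  expect_false(any(cands2$protein_a == "A" & cands2$protein_b == "B"))
  boundary <- as_net(pairs_tbl(c("A", "A", "B", "B"), c("S", "P", "S", "Q")))
  # A: {S,P}, B: {S,Q} -> b1 = 1, b2 = 2
  cb <- candidate_pairs(boundary)
  ab <- cb[cb$protein_a == "A" & cb$protein_b == "B", ]
  expect_equal(nrow(ab), 1L)
  expect_equal(ab$b1, 1L)
  expect_equal(ab$b2, 2L)
})

test_that("bits counts shared neighbors on the textbook graphs", {
  tri <- as_net(pairs_tbl(c("A", "A", "B"), c("B", "C", "C")))
  expect_equal(pair_bits(tri, "A", "B"), 1)
  star <- as_net(pairs_tbl(rep("H", 5), paste0("L", 1:5)))
  expect_equal(pair_bits(star, "L1", "L2"), 1)
  expect_error(pair_bits(star, "L1", "nope"), "absent")
})

test_that("specific bits follows its closed form and conventions", {
  net <- as_net(pairs_tbl(c("A", "A", "B", "B", "A", "B"),
                          c("s1", "s2", "s1", "s2", "u1", "u2")))
  # A: {s1,s2,u1}, B: {s1,s2,u2}: b1 = 2, b2 = 2
  expect_equal(pair_specific_bits(net, "A", "B"), 2 * -log(0.5))
  # identical neighbor sets: b2 = 0 so the log term vanishes
  twin <- as_net(pairs_tbl(c("A", "A", "B", "B"), c("s1", "s2", "s1", "s2")))
  expect_equal(pair_specific_bits(twin, "A", "B"), 0)
  # disjoint sets: b1 = 0 by convention
  disj <- as_net(pairs_tbl(c("A", "B"), c("x", "y")))
  expect_equal(pair_specific_bits(disj, "A", "B"), 0)
})

test_that("profile scores agree with brute-force set operations everywhere", {
  w <- generate_true_network(10, mean_degree = 3, seed = 1)
  net <- as_net(w$true_edges)
  sc <- second_order_scores(net, min_share_fraction = 0,
                            exclude_adjacent = FALSE)
  nodes <- network_nodes(net)
  cmb <- utils::combn(nodes, 2)
  for (i in seq_len(ncol(cmb))) {
    p1 <- cmb[1, i]; p2 <- cmb[2, i]
    ref <- brute_profile(net, p1, p2)
    row <- sc[sc$protein_a == min(p1, p2) & sc$protein_b == max(p1, p2), ]
    if (ref$b1 == 0) {
      expect_equal(nrow(row), 0L)  # pairs without shared neighbors not scored
    } else {
      expect_equal(row$b1, ref$b1)
      expect_equal(row$b2, ref$b2)
      expect_equal(pair_bits(net, p1, p2), ref$b1)
    }
  }
})

test_that("congruence matches the enumerated hypergeometric surprise", {
  w <- generate_true_network(12, mean_degree = 3, seed = 2)
  net <- as_net(w$true_edges)
  m <- length(network_nodes(net))
  sc <- second_order_scores(net, min_share_fraction = 0,
                            exclude_adjacent = FALSE, congruence = TRUE)
  for (i in seq_len(nrow(sc))) {
    p1 <- sc$protein_a[i]; p2 <- sc$protein_b[i]
    ns <- brute_profile(net, p1, p2)
    k1 <- length(setdiff(
      unique(c(net$protein_b[net$protein_a == p1],
               net$protein_a[net$protein_b == p1])), p2))
    k2 <- length(setdiff(
      unique(c(net$protein_b[net$protein_a == p2],
               net$protein_a[net$protein_b == p2])), p1))
    tail_p <- brute_hyper_tail(ns$b1, k2, m - 2 - k2, k1)
    expect_equal(sc$congruence[i], -log10(tail_p), tolerance = 1e-8)
    expect_gte(sc$congruence[i], 0)
  }
})

test_that("the three scores are symmetric in the pair", {
  w <- generate_true_network(15, mean_degree = 3, seed = 3)
  net <- as_net(w$true_edges)
  nodes <- network_nodes(net)
  for (i in 1:5) {
    p <- sample(nodes, 2)
    expect_equal(pair_bits(net, p[1], p[2]), pair_bits(net, p[2], p[1]))
    expect_equal(pair_specific_bits(net, p[1], p[2]),
                 pair_specific_bits(net, p[2], p[1]))
    expect_equal(pair_congruence(net, p[1], p[2]),
                 pair_congruence(net, p[2], p[1]))
  }
})

test_that("bits and specific bits behave near-identically in validation", {
  st <- build_study(n = 500, seed = 41)
  pg <- build_pg(st$integrated, 0.005)
  sc <- second_order_scores(pg, congruence = FALSE)
  expect_gt(nrow(sc), 20)
  # the two scores agree in ranking direction: desk-scale shared-neighbor
  # counts span a narrow range, so the check is on group-level behaviour
  # rather than a high rank correlation
  expect_gte(cor(sc$bits, sc$specific_bits, method = "spearman"), 0)
  if (any(sc$b1 >= 2)) {
    expect_gt(mean(sc$specific_bits[sc$b1 >= 2]),
              mean(sc$specific_bits[sc$b1 == 1]))
  }
  # and both rank the identical candidate set (they differ only in ordering)
  expect_identical(sc$bits, sc$b1)
})

test_that("second-order predictions exclude first-order edges and find new truth", {
  st <- build_study(n = 500, seed = 41)
  pg <- build_pg(st$integrated, 0.005)
  sc <- second_order_scores(pg, congruence = FALSE)
  pg_keys <- pair_key(pg$protein_a, pg$protein_b)
  expect_false(any(pair_key(sc$protein_a, sc$protein_b) %in% pg_keys))

  true_keys <- pair_key(st$world$true_edges$protein_a,
                        st$world$true_edges$protein_b)
  new_truth <- setdiff(true_keys, pg_keys)
  scored <- pair_key(sc$protein_a, sc$protein_b)
  n_nodes <- length(network_nodes(pg))
  hit <- sum(scored %in% new_truth)
  # odds of a scored pair being an unseen true edge vs the background rate
  bg <- length(new_truth) / choose(n_nodes, 2)
  rate <- hit / nrow(sc)
  expect_gt(rate, bg)
})

test_that("validation against KG gold standards reduces to the benchmark machinery", {
  st <- build_study(n = 500, seed = 41)
  pg <- build_pg(st$integrated, 0.005)
  sc <- second_order_scores(pg, congruence = FALSE)
  expect_gt(nrow(sc), 20)
  raw <- validate_second_order(sc, st$evidence, min_kg_evidence = 1,
                               n_random = 50, seed = 7,
                               drop_unstable = FALSE)
  expect_s3_class(raw, "pg_pr_curve")
  expect_gt(nrow(raw), 0)
  expect_true(all(diff(raw$recall) >= 0))
  filtered <- validate_second_order(sc, st$evidence, min_kg_evidence = 1,
                                    n_random = 50, seed = 7)
  expect_true(all(!(filtered$fp_sd > filtered$fp_mean / 3)))
  expect_lte(nrow(filtered), nrow(raw))
})
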