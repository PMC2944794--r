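triangle <- function() as_net(pairs_tbl(c("A", "A", "B"), c("B", "C", "C")))
star5 <- function() as_net(pairs_tbl(rep("H", 5), paste0("L", 1:5)))
path3 <- function() as_net(pairs_tbl(c("A", "B"), c("B", "C")))

test_that("degree histograms match the textbook graphs", {
  expect_equal(degree_histogram(triangle()),
               tibble::tibble(k = 2L, count = 3L))
  expect_equal(degree_histogram(star5()),
               tibble::tibble(k = c(1L, 5L), count = c(5L, 1L)))
  expect_equal(degree_histogram(path3()),
               tibble::tibble(k = 1:2, count = c(2L, 1L)))
  h <- degree_histogram(triangle())
  expect_equal(sum(h$k * h$count), 2 * nrow(triangle()))
})

test_that("power-law fitting recovers a noiseless exponent exactly", {
  k <- 1:50
  freq <- tibble::tibble(k = k, count = 1000 * k^-2.5)
  fit <- fit_power_law(freq)
  expect_equal(fit$gamma, 2.5, tolerance = 1e-10)
  expect_equal(abs(fit$r), 1, tolerance = 1e-10)

  uniform <- tibble::tibble(k = 1:10, count = rep(7, 10))
  expect_equal(fit_power_law(uniform)$gamma, 0, tolerance = 1e-10)
  expect_error(fit_power_law(tibble::tibble(k = 1:2, count = c(1, 2))), ">= 3")
})

test_that("clustering coefficients match hand enumeration", {
  cl_tri <- clustering(triangle())
  expect_equal(cl_tri$local$c, rep(1, 3))
  expect_equal(cl_tri$average, 1)

  cl_star <- clustering(star5())
  expect_equal(cl_star$average, 0)

  # square ABCD plus chord AC: chord endpoints see 2 of 3 neighbor pairs linked
  sq <- as_net(pairs_tbl(c("A", "B", "C", "A", "A"),
                         c("B", "C", "D", "D", "C")))
  cl <- clustering(sq)
  c_of <- setNames(cl$local$c, cl$local$protein)
  expect_equal(unname(c_of[c("A", "B", "C", "D")]), c(2/3, 1, 2/3, 1))
  expect_equal(cl$average, 5 / 6)
})

test_that("assortativity matches closed forms and the igraph cross-check", {
  expect_equal(assortativity(star5()), -1)
  complete4 <- as_net(pairs_tbl(c("A", "A", "A", "B", "B", "C"),
                                c("B", "C", "D", "C", "D", "D")))
  expect_true(is.na(assortativity(complete4)))

  cliq <- function(nodes) {
    cmb <- utils::combn(nodes, 2)
    pairs_tbl(cmb[1, ], cmb[2, ])
  }
  # joined unequal cliques: like-degree nodes dominate, so r_deg is positive
  two_cliques <- as_net(dplyr::bind_rows(cliq(paste0("a", 1:6)),
                                         cliq(paste0("b", 1:3)),
                                         pairs_tbl("a1", "b1")))
  expect_gt(assortativity(two_cliques), 0)
  expect_equal(assortativity(two_cliques), brute_assortativity(two_cliques))
  expect_equal(assortativity(two_cliques),
               igraph::assortativity_degree(as_igraph_oracle(two_cliques)),
               tolerance = 1e-10)

  w <- generate_true_network(150, mean_degree = 4, seed = 1)
  net <- as_net(w$true_edges)
  expect_equal(assortativity(net),
               igraph::assortativity_degree(as_igraph_oracle(net)),
               tolerance = 1e-10)
})

test_that("distance metrics work on the largest component only", {
  d <- distance_metrics(path3())
  expect_equal(d$char_path_length, 4 / 3)
  expect_equal(d$radius, 1)
  expect_equal(d$diameter, 2)

  complete4 <- as_net(pairs_tbl(c("A", "A", "A", "B", "B", "C"),
                                c("B", "C", "D", "C", "D", "D")))
  dc <- distance_metrics(complete4)
  expect_equal(dc$char_path_length, 1)
  expect_equal(dc$radius, 1)
  expect_equal(dc$diameter, 1)

  two_comp <- as_net(dplyr::bind_rows(
    pairs_tbl(c("A", "B", "C", "D"), c("B", "C", "D", "E")),  # 5-node path
    pairs_tbl(c("x", "y"), c("y", "z"))                        # 3-node path
  ))
  dt <- distance_metrics(two_comp)
  expect_equal(dt$component_size, 5)
  expect_equal(dt$diameter, 4)
  expect_true(dt$radius <= dt$diameter && dt$diameter <= 2 * dt$radius)
})

test_that("the degree-shape classifier separates the two null families", {
  er <- generate_true_network(2000, mean_degree = 10, model = "er", seed = 1)
  expect_identical(gaussian_degree_test(as_net(er$true_edges))$label,
                   "gaussian-like")
  pa <- generate_true_network(2000, mean_degree = 6, seed = 2)
  expect_identical(gaussian_degree_test(as_net(pa$true_edges))$label,
                   "heavy-tailed")
  five_equal <- tibble::tibble(k = 1:5, count = rep(4L, 5))
  expect_identical(gaussian_degree_test(five_equal)$label, "ambiguous")
  expect_error(gaussian_degree_test(tibble::tibble(k = 1:3, count = 1:3)),
               ">= 5")
})

test_that("all metrics agree with brute force on small graphs", {
  for (seed in 1:4) {
    w <- generate_true_network(25, mean_degree = 3, seed = seed)
    net <- as_net(w$true_edges)
    expect_equal(unname(network_degrees(net)),
                 unname(brute_degrees(net)[network_nodes(net)]))
    cl <- clustering(net)
    brute_c <- brute_clustering(net)
    expect_equal(setNames(cl$local$c, cl$local$protein)[names(brute_c)],
                 brute_c, tolerance = 1e-12)
    if (stats::sd(c(network_degrees(net)[net$protein_a],
                    network_degrees(net)[net$protein_b])) > 0) {
      expect_equal(assortativity(net), brute_assortativity(net),
                   tolerance = 1e-12)
    }
    # distances on the largest component
    g <- as_igraph_oracle(net)
    comp <- igraph::components(g)
    keep <- names(which(comp$membership == which.max(comp$csize)))
    sub <- net[net$protein_a %in% keep & net$protein_b %in% keep, ]
    bd <- brute_distances(sub)
    dm <- distance_metrics(net)
    expect_equal(dm$char_path_length, mean(bd[upper.tri(bd)]))
    expect_equal(dm$diameter, max(bd[is.finite(bd)]))
    expect_equal(dm$radius, min(apply(bd, 1, max)))
  }
})

test_that("weight randomization leaves every topology metric unchanged", {
  st <- build_study(n = 300, seed = 21)
  pg <- build_pg(st$integrated, 0.05)
  r <- randomize_weights(pg, seed = 9)
  s1 <- glance(topology_summary(pg))
  s2 <- glance(topology_summary(r))
  expect_equal(s1, s2)
})
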