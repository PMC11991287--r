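# Module detection, weight/confidence filters, the weak-ties spectrum and
# intra/inter-modular weights.

test_that("Louvain separates planted cliques and matches the exhaustive oracle", {
  net <- two_cliques(6)
  part <- detect_modules(net, seed = 3)
  oracle <- best_bipartition(net)
  expect_identical(canon_partition(part), canon_partition(oracle$membership))
  g <- grwnet:::as_igraph(net, weighted = FALSE)
  expect_equal(igraph::modularity(g, part), oracle$modularity, tolerance = 1e-12)

  full <- toy_net(t(combn(1:8, 2))[, 1], t(combn(1:8, 2))[, 2])
  expect_equal(length(unique(detect_modules(full, seed = 1))), 1L)

  expect_identical(detect_modules(ws1_fixture(300, seed = 4), seed = 7),
                   detect_modules(ws1_fixture(300, seed = 4), seed = 7))
  empty <- weighted_network(data.frame(from = integer(0), to = integer(0),
                                       weight = numeric(0)),
                            nodes = data.frame(id = "a"))
  expect_error(detect_modules(empty), "empty")
})

test_that("the global weight filter keeps the lowest weights with stable ties", {
  net <- toy_net(c(1, 1, 2, 3), c(2, 3, 4, 4), weight = c(3, 1, 4, 2))
  expect_identical(global_weight_filter(net, 100)$edges, net$edges)
  half <- global_weight_filter(net, 50)
  expect_equal(sort(half$edges$weight), c(1, 2))
  expect_identical(half$nodes, net$nodes)
  expect_error(global_weight_filter(net, 0), "percent")
  expect_error(global_weight_filter(net, 101), "percent")
  # many equal weights: retained count is exact and reproducible
  tied <- toy_net(rep(1, 10), 2:11, weight = rep(1, 10))
  expect_equal(nrow(global_weight_filter(tied, 37)$edges), ceiling(3.7))
  expect_identical(global_weight_filter(tied, 37)$edges,
                   global_weight_filter(tied, 37)$edges)
})

test_that("filters are nested across percentages", {
  net <- ws1_fixture(n = 300, seed = 5)
  for (f in list(global_weight_filter, confidence_filter)) {
    prev <- NULL
    for (pc in c(5, 20, 60, 100)) {
      cur <- paste(f(net, pc)$edges$from, f(net, pc)$edges$to)
      if (!is.null(prev)) expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("disparity-filter alpha matches the closed form and quadrature", {
  # closed form against direct numerical integration of the incomplete-beta
  # integral, over a grid of degrees and normalized weights
  for (k in c(2, 3, 7, 20, 100)) {
    for (f in c(0.01, 0.2, 0.5, 0.9, 0.99)) {
      quad <- 1 - (k - 1) * integrate(function(x) (1 - x)^(k - 2), 0, f,
                                      rel.tol = 1e-13)$value
      expect_lt(abs((1 - f)^(k - 1) - quad), 1e-10)
    }
  }
  # micro-examples on a star-plus-path toy
  net <- toy_net(c(1, 1, 2), c(2, 3, 3), weight = c(1, 1, 2))
  conf <- edge_confidence(net)
  expect_true(all(conf$alpha >= 0 & conf$alpha <= 1))
  # k = 2 endpoint with w/s = 0.5 -> alpha = 0.5
  expect_equal(conf$alpha_from[1], 0.5)
  # w/s = 1 would give alpha = 0 and w/s = 0 gives alpha = 1
  leaf <- toy_net(1, 2, weight = 5)
  cl <- edge_confidence(leaf)
  expect_equal(cl$alpha, 1)  # degree-1 endpoints are never significant
  chain <- toy_net(c(1, 2), c(2, 3), weight = c(1, 1e-12))
  cc <- edge_confidence(chain)
  expect_equal(cc$alpha_to[1], 1e-12, tolerance = 1e-4)  # w/s ~ 1 at node 2
})

test_that("weight and confidence filters coincide on a star graph", {
  # on a star, edge alpha comes from the hub and decreases with weight, so
  # confidence increases with weight and both rankings agree
  star <- toy_net(rep(1, 8), 2:9, weight = c(5, 3, 8, 1, 9, 2, 7, 4))
  conf <- edge_confidence(star)
  expect_true(all(diff(conf$confidence[order(conf$weight)]) > 0))
  for (pc in c(25, 50, 75)) {
    a <- global_weight_filter(star, pc)$edges
    b <- confidence_filter(star, pc)$edges
    expect_identical(a, b)
  }
})

test_that("intermodular density matches counting oracles", {
  net <- ws1_fixture(n = 200, seed = 12)
  one <- rep(1L, 200)
  expect_equal(intermodular_density(net, one), 0)
  each <- seq_len(200)
  expect_equal(intermodular_density(net, each), 1)
  # two triangles joined by one edge: 1 intermodular of 7 edges
  tri2 <- toy_net(c(1, 1, 2, 4, 4, 5, 3), c(2, 3, 3, 5, 6, 6, 4))
  part <- c(1, 1, 1, 2, 2, 2)
  expect_equal(intermodular_density(tri2, part), 1 / 7)
  empty <- weighted_network(data.frame(from = integer(0), to = integer(0),
                                       weight = numeric(0)), net$nodes)
  expect_warning(re <- intermodular_density(empty, one), "undefined")
  expect_true(is.na(re))
})

test_that("the weak-ties spectrum is normalized and flags single modules", {
  net <- ws1_fixture(n = 400, tau = 0.6, seed = 3)
  part <- detect_modules(net, seed = 1)
  for (f in c("weight", "confidence")) {
    sp <- weak_ties_spectrum(net, part, f)
    expect_equal(sp$rho[sp$percents == 100], 1)
    expect_true(sp$defined)
  }
  expect_warning(sp1 <- weak_ties_spectrum(net, rep(1L, 400), "weight"),
                 "single-module")
  expect_false(sp1$defined)
  expect_true(all(is.na(sp1$rho)))
})

test_that("weak ties concentrate between geometric modules (ensemble)", {
  rho1 <- vapply(1:5, function(s) {
    net <- ws1_fixture(n = 400, tau = 0.6, mean_degree = 12, seed = 100 + s)
    part <- detect_modules(net, seed = s)
    sp <- weak_ties_spectrum(net, part, "weight", percents = c(1, 50, 100))
    sp$rho[1]
  }, numeric(1))
  expect_gt(mean(rho1), 1)
})

test_that("intra- and inter-modular mean weights follow their definitions", {
  # module A: edges 2 and 4 (mean 3); module B: edge 4; bridge weight 1
  net <- toy_net(c(1, 1, 4, 5, 3), c(2, 3, 5, 6, 4),
                 weight = c(2, 4, 4, 4, 1))
  part <- c(1, 1, 1, 2, 2, 2)
  out <- intra_inter_mean_weights(net, part)
  expect_equal(unname(out["intra"]), mean(c(mean(c(2, 4)), 4)))
  expect_equal(unname(out["inter"]), 1)
  expect_error(intra_inter_mean_weights(net, rep(1L, 6)), "single module")
  # WS1 networks: intra stronger than inter on average
  diffs <- vapply(1:5, function(s) {
    n <- ws1_fixture(n = 400, tau = 0.6, mean_degree = 12, seed = 100 + s)
    p <- detect_modules(n, seed = s)
    v <- intra_inter_mean_weights(n, p)
    v["intra"] - v["inter"]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
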