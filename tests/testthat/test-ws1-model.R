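# The WS1 synthetic-network generator: hidden variables, gravity-law
# topology, geometry-coupled weights, calibrations and cohorts.

test_that("hidden strengths follow sigma = a * kappa^eta exactly", {
  p <- ws1_params(n_nodes = 2, a = 1, eta = 1,
                  kappa_law = kappa_values(c(2, 3)), seed = 1)
  nd <- sample_ws1_nodes(p)
  expect_equal(sort(nd$sigma), sort(nd$kappa))
  p2 <- ws1_params(n_nodes = 50, a = 2.5, eta = 0.7, seed = 3)
  nd2 <- sample_ws1_nodes(p2)
  expect_equal(nd2$sigma, 2.5 * nd2$kappa^0.7)
  expect_true(all(nd2$theta >= 0 & nd2$theta < 2 * pi))
})

test_that("parameter validation rejects out-of-domain values", {
  expect_error(ws1_params(beta = 1), "beta")
  expect_error(ws1_params(tau = 1), "tau")
  expect_error(ws1_params(a = -1), "positive")
  expect_error(ws1_params(kappa_law = kappa_power_law(gamma = 0.5)), "gamma")
  expect_error(ws1_params(kappa_law = kappa_values(c(1, -2))), "positive")
})

test_that("node sampling and full generation are deterministic given the seed", {
  p <- ws1_params(n_nodes = 300, seed = 11)
  expect_identical(sample_ws1_nodes(p), sample_ws1_nodes(p))
  n1 <- sample_ws1(p)
  n2 <- sample_ws1(p)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$nodes, n2$nodes)
  n3 <- sample_ws1(p, seed = 99)
  expect_false(identical(n1$edges, n3$edges))
})

test_that("sampled hidden degrees match the truncated power-law mean", {
  law <- kappa_power_law(2.7, 4, 100)
  # independent check of the closed form against quadrature
  dens_norm <- integrate(function(x) x^-2.7, 4, 100)$value
  mean_quad <- integrate(function(x) x * x^-2.7, 4, 100)$value / dens_norm
  expect_equal(grwnet:::kappa_law_mean(law), mean_quad, tolerance = 1e-8)
  p <- ws1_params(n_nodes = 5000, kappa_law = law, seed = 5)
  kap <- sample_ws1_nodes(p)$kappa
  se <- sd(kap) / sqrt(length(kap))
  expect_lt(abs(mean(kap) - mean_quad), 3 * se)
  expect_true(all(kap >= 4 & kap <= 100))
})

test_that("connection probability follows the gravity law", {
  p <- ws1_params(n_nodes = 100, beta = 2, mu = 0.05, seed = 1)
  R <- 100 / (2 * pi)
  # chi = 1: place two nodes so that d = mu * k_i * k_j
  kij <- c(4, 5)
  dth <- p$mu * prod(kij) / R
  expect_equal(connection_probability(0, dth, 4, 5, p), 0.5)
  # chi = 2 with beta = 2: p = 1 / (1 + 4)
  expect_equal(connection_probability(0, 2 * dth, 4, 5, p), 0.2)
  expect_equal(connection_probability(1.3, 1.3, 4, 5, p), 1)  # d = 0
  expect_error(connection_probability(0, 1, -1, 5, p), "hidden degrees")
  # monotone: decreasing in distance, increasing in kappa product
  dd <- seq(0.01, pi, length.out = 50)
  pv <- connection_probability(0, dd, 4, 5, p)
  expect_true(all(diff(pv) < 0))
  kk <- seq(1, 50, length.out = 25)
  pk <- connection_probability(0, 1, kk, 5, p)
  expect_true(all(diff(pk) > 0))
})

test_that("mu calibration is deterministic, near-linear, and hits the target", {
  p <- ws1_params(n_nodes = 500, beta = 2.5, seed = 7)
  nodes <- sample_ws1_nodes(p)
  mu1 <- calibrate_mu(p, 10, nodes = nodes)
  expect_identical(mu1, calibrate_mu(p, 10, nodes = nodes))
  mu2 <- calibrate_mu(p, 20, nodes = nodes)
  expect_gt(mu2 / mu1, 1.7)
  expect_lt(mu2 / mu1, 2.3)
  expect_error(calibrate_mu(p, 1000), "infeasible")
  # Monte-Carlo oracle: constant kappa, ensemble mean degree near target
  pc <- ws1_params(n_nodes = 500, beta = 2.5,
                   kappa_law = kappa_values(rep(10, 500)), seed = 2)
  nd <- sample_ws1_nodes(pc)
  pc$mu <- calibrate_mu(pc, 12, nodes = nd)
  kbar <- vapply(1:10, function(s) {
    mean(node_degrees(generate_topology(nd, pc, seed = s)))
  }, numeric(1))
  expect_lt(abs(mean(kbar) - 12) / 12, 0.05)
})

test_that("topology generation matches the Bernoulli law pair by pair", {
  # two nodes at chi = 1: edge occurs in about half of many realizations
  p <- ws1_params(n_nodes = 2, beta = 2.5, mu = 1 / 12, seed = 1,
                  kappa_law = kappa_values(c(3, 4)))
  nodes <- data.frame(id = c("a", "b"), theta = c(0, pi), kappa = c(3, 4),
                      sigma = c(3, 4))
  # d = R * pi = 1, chi = d / (mu * 12) = 1
  expect_equal(connection_probability(0, pi, 3, 4, p), 0.5)
  hits <- vapply(1:10000, function(s)
    nrow(generate_topology(nodes, p, seed = s)$edges), integer(1))
  expect_gt(binom.test(sum(hits), 10000, 0.5)$p.value, 1e-3)
  # large beta, chi < 1 (chi = 0.5): edge nearly always present
  p2 <- ws1_params(n_nodes = 2, beta = 50, mu = 2 / 12, seed = 1,
                   kappa_law = kappa_values(c(3, 4)))
  hits2 <- vapply(1:200, function(s)
    nrow(generate_topology(nodes, p2, seed = s)$edges), integer(1))
  expect_gte(mean(hits2), 0.99)
})

test_that("weights follow the WS1 closed form", {
  # tau = 0, nu = 1, sigma = kappa: all weights collapse to 1
  p <- ws1_params(n_nodes = 200, beta = 2.5, tau = 0, nu = 1, a = 1, eta = 1,
                  mean_degree = 10, seed = 4)
  net <- sample_ws1(p)
  expect_true(all(abs(net$edges$weight - 1) < 1e-12))

  # hand evaluation: sigma = kappa = 2 at distance 4 with tau = 0.5 -> w = 1
  n <- 10
  theta2 <- 4 / (n / (2 * pi))
  nodes <- data.frame(id = sprintf("v%d", 1:n),
                      theta = c(0, theta2, seq(4, 6, length.out = 8)),
                      kappa = 2, sigma = 2)
  p2 <- ws1_params(n_nodes = n, beta = 2.5, mu = 0.1, tau = 0.5, nu = 1,
                   kappa_law = kappa_values(rep(2, n)), seed = 1)
  net2 <- weighted_network(data.frame(from = 1, to = 2, weight = 1), nodes)
  w <- assign_weights(net2, p2)$edges$weight
  expect_equal(w, 1, tolerance = 1e-12)

  # doubling nu doubles every weight
  p3 <- p2; p3$nu <- 2
  expect_equal(assign_weights(net2, p3)$edges$weight, 2 * w, tolerance = 1e-12)
})

test_that("nu calibration equates mean strength and mean hidden strength", {
  net <- ws1_fixture(n = 500, seed = 21)
  p <- attr(net, "params")
  expect_equal(mean(node_strengths(net)), mean(net$nodes$sigma),
               tolerance = 1e-10)
  # linearity: doubling the calibrated nu doubles the strength ratio
  p2 <- p; p2$nu <- 2 * p$nu
  net2 <- assign_weights(net, p2)
  expect_equal(mean(node_strengths(net2)) / mean(net2$nodes$sigma), 2,
               tolerance = 1e-10)
  expect_error(calibrate_nu(weighted_network(
    data.frame(from = integer(0), to = integer(0), weight = numeric(0)),
    nodes = net$nodes), p), "empty")
})

test_that("geometry coupling makes weights decay with distance at fixed kappa", {
  p <- ws1_params(n_nodes = 600, beta = 2.5, tau = 0.6, mean_degree = 10,
                  kappa_law = kappa_values(rep(8, 600)), seed = 9)
  net <- sample_ws1(p)
  d <- grwnet:::edge_arc_distances(net)
  expect_lt(cor(net$edges$weight, d, method = "spearman"), -0.99)
})

test_that("mean clustering is non-decreasing in beta (ensemble)", {
  cc <- vapply(c(1.5, 2.5, 5, 10), function(beta) {
    mean(vapply(1:5, function(s) {
      p <- ws1_params(n_nodes = 400, beta = beta, mean_degree = 12, seed = s)
      g <- grwnet:::as_igraph(sample_ws1(p), weighted = FALSE)
      igraph::transitivity(g, type = "localaverage")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(cc) > 0))
})

test_that("cohorts share the node set and per-edge length proxies", {
  p <- ws1_params(n_nodes = 150, mean_degree = 10, seed = 31)
  coh <- generate_cohort(p, n_subjects = 4, subject_variability = 0.1, seed = 5)
  expect_length(coh$subjects, 4)
  for (net in coh$subjects) {
    expect_identical(net$nodes$id, coh$nodes$id)
    expect_identical(net$nodes$theta, coh$nodes$theta)
    expect_identical(net$nodes$x, coh$nodes$x)
    expect_identical(net$nodes$hemisphere, coh$nodes$hemisphere)
  }
  # degenerate cohort: zero variability and one shared seed
  coh0 <- generate_cohort(p, n_subjects = 3, subject_variability = 0,
                          seed = 5, subject_seeds = c(17L, 17L, 17L))
  expect_identical(coh0$subjects[[1]]$edges, coh0$subjects[[2]]$edges)
  expect_identical(coh0$subjects[[2]]$edges, coh0$subjects[[3]]$edges)
})
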