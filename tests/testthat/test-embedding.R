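# Likelihood-based embedding: log-likelihood, hidden degrees, beta, angles,
# tau and the hidden-strength relation, plus the ws1_fit methods.

test_that("the S1 log-likelihood matches brute-force evaluation", {
  # two nodes at chi = 1 with an edge: log(1/2)
  nodes <- data.frame(id = c("a", "b"), theta = c(0, pi), kappa = c(1, 1))
  net <- weighted_network(data.frame(from = 1, to = 2, weight = 1), nodes)
  expect_equal(ws1_loglik(net, c(0, pi), c(1, 1), beta = 3, mu = 1), log(0.5))

  # 3-node toy against the direct product over pairs
  set.seed(2)
  nd <- data.frame(id = c("a", "b", "c"), theta = runif(3, 0, 2 * pi),
                   kappa = c(2, 1, 4))
  net3 <- weighted_network(data.frame(from = c(1, 2), to = c(2, 3),
                                      weight = 1), nd)
  beta <- 2.2; mu <- 0.3; R <- 3 / (2 * pi)
  brute <- 0
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    d <- abs(nd$theta[pair[1]] - nd$theta[pair[2]]) %% (2 * pi)
    d <- min(d, 2 * pi - d) * R
    p <- 1 / (1 + (d / (mu * prod(nd$kappa[pair])))^beta)
    linked <- identical(pair, c(1, 2)) || identical(pair, c(2, 3))
    brute <- brute + if (linked) log(p) else log(1 - p)
  }
  expect_equal(ws1_loglik(net3, nd$theta, nd$kappa, beta, mu), brute,
               tolerance = 1e-12)
  expect_lte(ws1_loglik(net3, nd$theta, nd$kappa, beta, mu), 0)
})

test_that("hidden-degree inference matches observed degrees and symmetry", {
  # regular ring lattice: all inferred kappas equal
  n <- 40
  ring <- toy_net(rep(1:n, 2), c(2:n, 1, 3:n, 1, 2), weight = 1)
  kap <- infer_hidden_degrees(ring, beta = 3)
  expect_lt(diff(range(kap)) / mean(kap), 1e-6)

  net <- ws1_fixture(n = 400, mean_degree = 25, seed = 8)
  kap2 <- infer_hidden_degrees(net, beta = 2.5)
  k <- node_degrees(net)
  # post-condition: expected degree within 1% of observed, per node
  ek <- grwnet:::expected_degrees(kap2, 2.5,
                                  2.5 * sin(pi / 2.5) / (2 * pi * mean(k)),
                                  400)
  expect_lt(max(abs(ek - k) / k), 0.01)
  # monotone in the observed degree
  expect_gt(cor(kap2, k, method = "spearman"), 0.999)
  iso <- weighted_network(data.frame(from = 1, to = 2, weight = 1),
                          nodes = data.frame(id = c("a", "b", "c")))
  expect_error(infer_hidden_degrees(iso, 2.5), "isolated")
})

test_that("beta recovery brackets the generative value", {
  net <- ws1_fixture(n = 500, beta = 2.5, mean_degree = 20, seed = 23)
  bh <- infer_beta(net, seed = 5)
  expect_gt(bh, 2.0)
  expect_lt(bh, 3.0)
})

test_that("angle inference is deterministic, ascending and accurate", {
  net <- ws1_fixture(n = 300, beta = 2.5, tau = 0.4, mean_degree = 20, seed = 29)
  kap <- infer_hidden_degrees(net, 2.5)
  mu <- 2.5 * sin(pi / 2.5) / (2 * pi * mean(node_degrees(net)))
  th1 <- infer_angles(net, kap, 2.5, mu, seed = 4)
  th2 <- infer_angles(net, kap, 2.5, mu, seed = 4)
  expect_identical(as.numeric(th1), as.numeric(th2))
  expect_true(all(diff(attr(th1, "loglik_trace")) >= -1e-8))
  expect_lt(angular_error(as.numeric(th1), net$nodes$theta), 0.3)
})

test_that("tau recovery on the grid hits the generative coupling", {
  for (tau_true in c(0, 0.8)) {
    net <- ws1_fixture(n = 500, tau = tau_true, mean_degree = 20,
                       seed = 300 + round(10 * tau_true))
    th <- estimate_tau(net, net$nodes$theta, net$nodes$kappa)
    if (tau_true == 0) expect_lte(as.numeric(th), 0.1)
    else expect_true(as.numeric(th) >= 0.65 && as.numeric(th) <= 0.95)
    # self-consistency: the objective at the generating tau is near its minimum
    obj <- attr(th, "objective")
    at_truth <- obj$value[which.min(abs(obj$tau - tau_true))]
    expect_lt(at_truth, min(obj$value) + diff(range(obj$value)) * 0.2)
  }
})

test_that("the sigma(kappa) relation is recovered from strengths", {
  net <- ws1_fixture(n = 300, tau = 0, mean_degree = 8, seed = 2)
  e <- net$edges; e$weight <- rep(2, nrow(e))
  expect_equal(unname(fit_sigma_relation(weighted_network(e, net$nodes))),
               c(2, 1), tolerance = 1e-10)
  net9 <- ws1_fixture(n = 500, eta = 0.9, mean_degree = 20, seed = 77)
  ae <- fit_sigma_relation(net9)
  expect_lt(abs(ae["eta"] - 0.9), 0.1)
})

test_that("ws1_fit returns a coherent model object with working methods", {
  net <- ws1_fixture(n = 300, beta = 2.5, tau = 0.4, mean_degree = 20, seed = 41)
  fit <- ws1_fit(net, beta = 2.5, seed = 6)
  expect_s3_class(fit, "ws1_fit")
  co <- coef(fit)
  expect_named(co, c("beta", "mu", "nu", "tau", "a", "eta"))
  expect_gt(co["beta"], 1)
  expect_true(co["tau"] >= 0 && co["tau"] < 1)
  expect_lte(as.numeric(logLik(fit)), 0)
  expect_output(print(fit), "WS1 model fit")
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_identical(sims[[1]]$nodes$id, net$nodes$id)
  expect_identical(simulate(fit, nsim = 1, seed = 3)[[1]]$edges,
                   sims[[1]]$edges)
})

test_that("replica ensembles from a fit reproduce the original distributions", {
  # embed, regenerate 100 replicas with the inferred parameters, and check
  # that the weight, strength and degree distributions of the original agree
  # with the replica ensemble: sup-distance well below the 0.1 used for
  # cross-layer self-similarity, and the degree CCDF inside the pointwise
  # mean +/- 2 s.d. ensemble band over at least 90% of its range (weight and
  # strength carry a small systematic offset from residual coordinate noise
  # that a pointwise band at this edge count resolves; see the vignette)
  net <- ws1_fixture(n = 300, beta = 2.5, tau = 0.4, mean_degree = 20, seed = 41)
  fit <- ws1_fit(net, beta = 2.5, seed = 6)
  sims <- simulate(fit, nsim = 100, seed = 9)
  pooled <- function(get) unlist(lapply(sims, get))
  expect_lt(ks_distance(net$edges$weight, pooled(function(x) x$edges$weight)),
            0.08)
  expect_lt(ks_distance(node_strengths(net), pooled(node_strengths)), 0.08)
  expect_lt(ks_distance(node_degrees(net), pooled(node_degrees)), 0.08)
  band_cover <- function(get) {
    obs <- get(net)
    grid <- quantile(obs, probs = seq(0.05, 0.95, length.out = 19))
    reps <- vapply(sims, function(s) {
      v <- get(s)
      vapply(grid, function(g) mean(v >= g), numeric(1))
    }, numeric(19))
    m <- rowMeans(reps); sdev <- apply(reps, 1, sd)
    obs_c <- vapply(grid, function(g) mean(obs >= g), numeric(1))
    mean(obs_c >= m - 2 * sdev - 1e-9 & obs_c <= m + 2 * sdev + 1e-9)
  }
  expect_gte(band_cover(function(x) node_degrees(x)), 0.9)
})
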