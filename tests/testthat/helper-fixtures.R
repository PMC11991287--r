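# Fixture builders and independent oracles used across test files.

# Small network from an edge data frame (ids optional).
toy_net <- function(from, to, weight = 1, nodes = NULL) {
  weighted_network(data.frame(from = from, to = to, weight = weight),
                   nodes = nodes)
}

# Two k-cliques joined by a single bridge edge.
two_cliques <- function(k) {
  e1 <- t(combn(seq_len(k), 2))
  e2 <- t(combn(seq_len(k) + k, 2))
  toy_net(c(e1[, 1], e2[, 1], 1L), c(e1[, 2], e2[, 2], k + 1L))
}

# Literal stick-breaking Monte Carlo for the disparity null: drop k-1 uniform
# points in [0, 1] and use the subinterval lengths as normalized weights.
# Returns the sampled disparity values Upsilon = k * sum(x^2).
stick_breaking_upsilon <- function(k, reps, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    if (k == 1) return(rep(1, reps))
    u <- matrix(runif(reps * (k - 1)), nrow = reps)
    u <- matrix(u[order(row(u), u)], nrow = reps, byrow = TRUE)
    x <- cbind(u[, 1], if (k > 2) u[, -1, drop = FALSE] -
                 u[, -(k - 1), drop = FALSE], 1 - u[, k - 1])
    k * rowSums(x^2)
  })
}

# Exhaustive best-modularity bipartition of a small network (<= ~16 nodes);
# independent oracle for community detection.
best_bipartition <- function(net) {
  n <- nrow(net$nodes)
  stopifnot(n <= 16)
  g <- igraph::graph_from_edgelist(as.matrix(net$edges[, c("from", "to")]),
                                   directed = FALSE)
  best_q <- -Inf
  best <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    memb <- c(1L, as.integer(intToBits(mask))[seq_len(n - 1)] + 1L)
    q <- igraph::modularity(g, memb)
    if (q > best_q) { best_q <- q; best <- memb }
  }
  list(membership = best, modularity = best_q)
}

# Canonical partition labels, for comparing partitions up to relabeling.
canon_partition <- function(p) as.integer(factor(p, levels = unique(p)))

# Small WS1 network memoised per test run.
local({
  cache <- new.env(parent = emptyenv())
  ws1_fixture <<- function(n = 500, beta = 2.5, tau = 0.5, mean_degree = 25,
                           eta = 0.9, seed = 1) {
    key <- paste(n, beta, tau, mean_degree, eta, seed, sep = "_")
    if (is.null(cache[[key]])) {
      p <- ws1_params(n_nodes = n, beta = beta, tau = tau,
                      mean_degree = mean_degree, eta = eta, seed = seed)
      cache[[key]] <- sample_ws1(p)
    }
    cache[[key]]
  }
})

# Mean absolute angular error after the best rotation/reflection alignment.
angular_error <- function(est, true) {
  best <- Inf
  for (refl in c(FALSE, TRUE)) {
    e <- if (refl) (2 * pi - est) %% (2 * pi) else est
    for (rot in seq(0, 2 * pi, length.out = 721)) {
      d <- abs(((e + rot) - true + pi) %% (2 * pi) - pi)
      best <- min(best, mean(d))
    }
  }
  best
}
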