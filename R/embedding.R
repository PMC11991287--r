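# Simplified likelihood-based inference of the S1/WS1 parameters of an
# observed network: hidden degrees (fixed point on expected degrees), beta
# (clustering match), angular coordinates (spectral initialization refined by
# per-node likelihood search), the weight-geometry coupling tau (grid search
# on weight-distance profiles) and the hidden-strength relation sigma = a k^eta.

#' S1 log-likelihood of an observed topology
#'
#' `sum_{i<j} [A_ij log p_ij + (1 - A_ij) log(1 - p_ij)]` with the S1
#' gravity-law connection probability. Returns `-Inf` when an existing edge
#' has probability 0 (or a non-edge probability 1).
#'
#' @param network A `wnet` (only its topology is used).
#' @param thetas,kappas Node coordinates and hidden degrees.
#' @param beta,mu Global model parameters.
#' @return The log-likelihood (a non-positive scalar, possibly `-Inf`).
#' @export
ws1_loglik <- function(network, thetas, kappas, beta, mu) {
  n <- n_nodes(network)
  stopifnot(length(thetas) == n, length(kappas) == n, all(kappas > 0), beta > 1)
  R <- n / (2 * pi)
  pr <- pair_indices(n)
  chi <- R * delta_theta(thetas[pr$i], thetas[pr$j]) /
    (mu * kappas[pr$i] * kappas[pr$j])
  lchib <- beta * log(chi)  # -Inf at chi = 0
  log_p <- -log1p(exp(pmin(lchib, 700)))
  log_q <- lchib + log_p    # log(1 - p) = log(chi^beta) - log(1 + chi^beta)
  # edge lookup: linear index of (i, j), i < j, within the pair enumeration
  adj <- logical(length(chi))
  epos <- pair_linear_index(network$edges$from, network$edges$to, n)
  adj[epos] <- TRUE
  ll <- sum(ifelse(adj, log_p, log_q))
  if (is.nan(ll)) -Inf else ll
}

# Re-adjust hidden degrees conditional on fixed angular coordinates, so that
# each node's expected degree at the embedded positions matches its observed
# degree (the embedding clusters connected pairs, which would otherwise
# inflate regenerated degrees).
adjust_kappas_given_angles <- function(network, theta, kappa, beta, mu,
                                       tol = 0.01, max_iter = 100L) {
  n <- n_nodes(network)
  k <- node_degrees(network)
  R <- n / (2 * pi)
  dth <- abs(outer(theta, theta, "-")) %% (2 * pi)
  D <- R * pmin(dth, 2 * pi - dth)
  for (it in seq_len(max_iter)) {
    chi <- D / (mu * outer(kappa, kappa))
    P <- 1 / (1 + chi^beta)
    diag(P) <- 0
    ek <- rowSums(P)
    if (max(abs(ek - k) / k) < tol) break
    kappa <- kappa * (k / ek)^0.5
  }
  kappa
}

# Position of the pair (i, j), i < j, in the pair_indices(n) enumeration.
pair_linear_index <- function(i, j, n) {
  offset <- (i - 1) * n - (i - 1) * i / 2
  as.integer(offset + (j - i))
}

# Expected degrees under the S1 model with uniform angles, by Gauss-Legendre
# quadrature of the connection probability over the angular separation.
expected_degrees <- function(kappas, beta, mu, n, gl = NULL) {
  if (is.null(gl)) gl <- pracma::gaussLegendre(48, 0, pi)
  R <- n / (2 * pi)
  P <- matrix(0, length(kappas), length(kappas))
  K <- mu * outer(kappas, kappas)
  for (g in seq_along(gl$x)) {
    P <- P + (gl$w[g] / pi) / (1 + (R * gl$x[g] / K)^beta)
  }
  rowSums(P) - diag(P)
}

#' Infer hidden degrees
#'
#' Damped multiplicative fixed-point iteration equating each node's expected
#' degree under the model (with uniform angles) to its observed degree, to a
#' relative tolerance of 1% per node.
#'
#' @param network A `wnet` with no isolated nodes.
#' @param beta Coupling/clustering parameter.
#' @param mu Average-degree parameter; the closed form
#'   `beta sin(pi/beta) / (2 pi <k>)` when omitted.
#' @param tol Per-node relative tolerance on the expected degree.
#' @param max_iter Iteration cap.
#' @return Numeric vector of hidden degrees.
#' @export
infer_hidden_degrees <- function(network, beta, mu = NULL, tol = 0.01,
                                 max_iter = 200L) {
  k <- node_degrees(network)
  if (any(k == 0)) stop("network has isolated nodes; hidden degrees undefined")
  n <- n_nodes(network)
  if (is.null(mu)) mu <- beta * sin(pi / beta) / (2 * pi * mean(k))
  gl <- pracma::gaussLegendre(48, 0, pi)
  kappa <- as.numeric(k)
  for (it in seq_len(max_iter)) {
    ek <- expected_degrees(kappa, beta, mu, n, gl)
    rel <- abs(ek - k) / k
    if (max(rel) < tol) return(kappa)
    kappa <- kappa * (k / ek)^0.5  # damping 0.5
  }
  stop("hidden-degree inference did not converge; max residual ",
       format(max(abs(ek - k) / k), digits = 3))
}

#' Infer the coupling parameter beta
#'
#' Bisection on `beta` matching the model's ensemble mean local clustering
#' coefficient (networks generated with the inferred hidden degrees and
#' uniform angles) to the observed one. Clustering is monotone increasing in
#' `beta`, which makes the bisection well posed; hitting a bracket boundary
#' is flagged with a warning.
#'
#' @param network A `wnet` containing at least one triangle.
#' @param beta_range Bracket for the search.
#' @param n_reps Networks generated per candidate `beta`.
#' @param tol Absolute tolerance on the clustering match.
#' @param seed Integer seed (generation is deterministic given it).
#' @return The estimated `beta`.
#' @export
infer_beta <- function(network, beta_range = c(1.2, 12), n_reps = 3,
                       tol = 0.01, seed = 1L) {
  g <- as_igraph(network, weighted = FALSE)
  c_obs <- igraph::transitivity(g, type = "localaverage")
  if (!is.finite(c_obs) || c_obs <= 0) stop("observed clustering undefined or zero")
  n <- n_nodes(network)
  k_mean <- mean(node_degrees(network))

  model_clustering <- function(beta, rep_seed) {
    mu <- beta * sin(pi / beta) / (2 * pi * k_mean)
    kap <- infer_hidden_degrees(network, beta, mu, tol = 0.02, max_iter = 100L)
    cc <- numeric(n_reps)
    seeds <- derive_seeds(rep_seed, n_reps)
    for (q in seq_len(n_reps)) {
      nodes <- data.frame(id = sprintf("v%d", seq_len(n)),
                          theta = with_seed(seeds[q], runif(n, 0, 2 * pi)),
                          kappa = kap, sigma = kap)
      p <- ws1_params(n_nodes = n, beta = beta, mu = mu, tau = 0,
                      kappa_law = kappa_values(kap), seed = seeds[q])
      net <- generate_topology(nodes, p, seed = seeds[q])
      cc[q] <- igraph::transitivity(as_igraph(net, weighted = FALSE),
                                    type = "localaverage")
    }
    mean(cc, na.rm = TRUE)
  }

  lo <- beta_range[1]; hi <- beta_range[2]
  seeds <- derive_seeds(seed, 30L)
  c_lo <- model_clustering(lo, seeds[1])
  c_hi <- model_clustering(hi, seeds[2])
  if (c_obs <= c_lo) {
    warning("observed clustering at or below the model's lower bracket; returning boundary")
    return(lo)
  }
  if (c_obs >= c_hi) {
    warning("observed clustering at or above the model's upper bracket; returning boundary")
    return(hi)
  }
  for (it in seq_len(12L)) {
    mid <- sqrt(lo * hi)
    c_mid <- model_clustering(mid, seeds[2L + it])
    if (abs(c_mid - c_obs) < tol) return(mid)
    if (c_mid < c_obs) lo <- mid else hi <- mid
    if (hi / lo < 1.02) break
  }
  sqrt(lo * hi)
}

#' Infer angular coordinates
#'
#' Spectral initialization (the leading non-trivial eigenvector pair of the
#' symmetrically normalized adjacency operator, mapped to the circle by
#' `atan2`), refined by sweeps of per-node likelihood search over candidate
#' angles. Only improving moves are accepted, so the total log-likelihood is
#' non-decreasing over iterations; sweeps stop when the gain per sweep drops
#' below `tol` (after at least `min_sweeps`).
#'
#' @param network A `wnet`.
#' @param kappas,beta,mu Model parameters (see [infer_hidden_degrees()],
#'   [infer_beta()]).
#' @param seed Integer seed (sweep order).
#' @param n_candidates Candidate angles per node and sweep.
#' @param min_sweeps,max_sweeps,tol Sweep control.
#' @return Numeric vector of angles in `[0, 2 pi)`, with the attained
#'   log-likelihood in `attr(, "loglik")` and its per-sweep trace in
#'   `attr(, "loglik_trace")`.
#' @export
infer_angles <- function(network, kappas, beta, mu, seed = 1L,
                         n_candidates = 24L, min_sweeps = 2L, max_sweeps = 12L,
                         tol = 1e-4) {
  n <- n_nodes(network)
  A <- matrix(0, n, n)
  A[cbind(network$edges$from, network$edges$to)] <- 1
  A <- A + t(A)
  d <- pmax(rowSums(A), 1)
  L <- A / sqrt(outer(d, d))
  ev <- eigen(L, symmetric = TRUE)
  theta <- atan2(ev$vectors[, 3] / sqrt(d), ev$vectors[, 2] / sqrt(d)) %% (2 * pi)

  R <- n / (2 * pi)
  local_ll <- function(th_cand, i) {
    # log-likelihood contribution of node i at each candidate angle
    dth <- abs(outer(th_cand, theta[-i], "-")) %% (2 * pi)
    dth <- pmin(dth, 2 * pi - dth)
    inv_scale <- 1 / (mu * kappas[i] * kappas[-i])
    chi <- R * dth * matrix(inv_scale, nrow(dth), length(inv_scale), byrow = TRUE)
    lchib <- beta * log(pmax(chi, 1e-300))
    lp <- -log1p(exp(pmin(lchib, 700)))
    lq <- lchib + lp
    ai <- A[i, -i] == 1
    rowSums(lp[, ai, drop = FALSE]) + rowSums(lq[, !ai, drop = FALSE])
  }
  total_ll <- function() ws1_loglik(network, theta, kappas, beta, mu)

  grid <- seq(0, 2 * pi, length.out = n_candidates + 1L)[-1L]
  ll <- total_ll()
  trace <- ll
  seeds <- derive_seeds(seed, max_sweeps)
  for (sw in seq_len(max_sweeps)) {
    sweep_rng <- with_seed(seeds[sw], list(ord = sample.int(n),
                                           rot = runif(n, 0, 2 * pi / n_candidates)))
    for (i in sweep_rng$ord) {
      # per-node rotation of the candidate grid avoids distinct nodes
      # collapsing onto identical angles (zero inferred distances)
      cand <- c(theta[i], (grid + sweep_rng$rot[i]) %% (2 * pi),
                (theta[i] + pi / n_candidates * c(-0.3, 0.3)) %% (2 * pi))
      lls <- local_ll(cand, i)
      theta[i] <- cand[which.max(lls)]
    }
    ll_new <- total_ll()
    trace <- c(trace, ll_new)
    gain <- ll_new - ll
    ll <- ll_new
    if (sw >= min_sweeps && gain < tol) break
  }
  structure(theta %% (2 * pi), loglik = ll, loglik_trace = trace)
}

#' Estimate the weight-geometry coupling tau
#'
#' Grid search on `tau` in `{0, 0.05, ..., 0.95}` minimizing the L2 distance
#' between the log-binned mean log-weight versus distance curve of the data
#' and the curve of model weights regenerated on the observed topology with
#' the same coordinates (noiseless weights are deterministic given the
#' topology, so no replica averaging is needed). The regenerated weights are
#' rescaled to the observed mean weight, removing the overall scale `nu`
#' from the comparison.
#'
#' @param network A weighted `wnet`.
#' @param thetas,kappas Node coordinates and hidden degrees.
#' @param sigmas Hidden strengths; `a * k^eta` from
#'   [fit_sigma_relation()] when omitted.
#' @param tau_grid Candidate values.
#' @param n_bins Distance bins for the profile.
#' @param method `"profile"` (the default, described above) or `"marginal"`:
#'   the Kolmogorov-Smirnov distance between the rescaled observed and
#'   regenerated weight distributions. The marginal objective is robust to
#'   noise in inferred coordinates (which attenuates the profile slope but
#'   leaves the distance distribution, and hence the weight spread,
#'   faithful), and is what [ws1_fit()] uses.
#' @return The estimated `tau`, with the objective curve in
#'   `attr(, "objective")`. A flat objective is flagged with a warning and
#'   the grid midpoint returned.
#' @export
estimate_tau <- function(network, thetas, kappas, sigmas = NULL,
                         tau_grid = seq(0, 0.95, by = 0.05), n_bins = 20,
                         method = c("profile", "marginal")) {
  method <- match.arg(method)
  n <- n_nodes(network)
  e <- network$edges
  R <- n / (2 * pi)
  d <- R * delta_theta(thetas[e$from], thetas[e$to])
  if (any(d <= 0)) d <- pmax(d, min(d[d > 0]) * 1e-6)
  if (is.null(sigmas)) {
    fit <- fit_sigma_relation(network)
    k <- node_degrees(network)
    sigmas <- fit["a"] * pmax(k, 1)^fit["eta"]
  }
  obs_curve <- binned_curve(d, log(e$weight), n_bins = n_bins)
  kp <- kappas[e$from] * kappas[e$to]
  sp <- sigmas[e$from] * sigmas[e$to]
  objective <- vapply(tau_grid, function(tau) {
    w_mod <- sp / (kp^(1 - tau) * d^tau)
    w_mod <- w_mod * mean(e$weight) / mean(w_mod)
    if (method == "marginal") {
      return(ks_distance(e$weight / mean(e$weight), w_mod / mean(w_mod)))
    }
    mod_curve <- binned_curve(d, log(w_mod), n_bins = n_bins)
    common <- intersect(obs_curve$x, mod_curve$x)
    oi <- match(common, obs_curve$x); mi <- match(common, mod_curve$x)
    sqrt(mean((obs_curve$mean[oi] - mod_curve$mean[mi])^2))
  }, numeric(1))
  if (diff(range(objective)) < 1e-10) {
    warning("flat tau objective; returning the grid midpoint")
    tau_hat <- tau_grid[ceiling(length(tau_grid) / 2)]
  } else {
    tau_hat <- tau_grid[which.min(objective)]
  }
  structure(tau_hat, objective = data.frame(tau = tau_grid, value = objective))
}

#' Fit the hidden-strength relation sigma = a * kappa^eta
#'
#' Log-log regression of the average strength per degree class (see
#' [strength_degree_profile()]), using observed degrees and strengths as
#' proxies of the hidden variables.
#'
#' @param network A weighted `wnet`.
#' @return Named vector `c(a = ..., eta = ...)`.
#' @export
fit_sigma_relation <- function(network) {
  prof <- strength_degree_profile(network)
  if (!prof$eta_defined) stop("a single degree class cannot identify eta")
  c(a = prof$a, eta = prof$eta)
}

#' Fit the WS1 model to a weighted network
#'
#' Full simplified embedding pipeline: `beta` from the clustering match,
#' `mu` from the closed form at the observed mean degree, hidden degrees
#' from the expected-degree fixed point, angular coordinates from
#' likelihood refinement of a spectral start, `(a, eta)` from the
#' strength-degree relation, hidden strengths `sigma = a kappa^eta`, `tau`
#' from the weight-distance grid search, and `nu` matching the observed mean
#' weight on the observed topology.
#'
#' @param network A weighted `wnet`.
#' @param beta Optionally fix `beta` instead of inferring it.
#' @param seed Integer seed controlling every stochastic stage.
#' @param ... Passed on to [infer_angles()].
#' @return An object of class `ws1_fit` with elements `theta`, `kappa`,
#'   `sigma`, `beta`, `mu`, `nu`, `tau`, `a`, `eta`, `loglik`, `network`.
#' @seealso [simulate.ws1_fit()] for generating synthetic replicas.
#' @export
ws1_fit <- function(network, beta = NULL, seed = 1L, ...) {
  stopifnot(inherits(network, "wnet"), n_edges(network) > 0L)
  seeds <- derive_seeds(seed, 4L)
  if (is.null(beta)) beta <- infer_beta(network, seed = seeds[1])
  k_mean <- mean(node_degrees(network))
  mu <- beta * sin(pi / beta) / (2 * pi * k_mean)
  kappa <- infer_hidden_degrees(network, beta, mu)
  theta <- infer_angles(network, kappa, beta, mu, seed = seeds[2], ...)
  ll <- attr(theta, "loglik")
  kappa <- adjust_kappas_given_angles(network, as.numeric(theta), kappa,
                                      beta, mu)
  ae <- fit_sigma_relation(network)
  sigma <- ae["a"] * kappa^ae["eta"]
  tau <- estimate_tau(network, theta, kappa, sigmas = sigma,
                      method = "marginal")
  # nu matching the observed mean weight on the observed topology
  e <- network$edges
  n <- n_nodes(network)
  d <- pmax(n / (2 * pi) * delta_theta(theta[e$from], theta[e$to]), 1e-12)
  w_unit <- (sigma[e$from] * sigma[e$to]) /
    ((kappa[e$from] * kappa[e$to])^(1 - as.numeric(tau)) * d^as.numeric(tau))
  nu <- mean(e$weight) / mean(w_unit)
  structure(list(theta = as.numeric(theta), kappa = kappa, sigma = unname(sigma),
                 beta = beta, mu = mu, nu = nu, tau = as.numeric(tau),
                 a = unname(ae["a"]), eta = unname(ae["eta"]),
                 loglik = ll, tau_objective = attr(tau, "objective"),
                 network = network),
            class = "ws1_fit")
}

#' @export
print.ws1_fit <- function(x, ...) {
  cat("WS1 model fit\n")
  cat(sprintf("  %d nodes, %d edges\n", n_nodes(x$network), n_edges(x$network)))
  cat(sprintf("  beta = %.3f, mu = %.4g, tau = %.2f, nu = %.4g\n",
              x$beta, x$mu, x$tau, x$nu))
  cat(sprintf("  sigma = a kappa^eta with a = %.3g, eta = %.3f\n", x$a, x$eta))
  cat(sprintf("  log-likelihood = %.2f\n", x$loglik))
  invisible(x)
}

#' @export
summary.ws1_fit <- function(object, ...) {
  k <- node_degrees(object$network)
  cat("WS1 model fit\n")
  print(coef(object))
  cat(sprintf("kappa range [%.3g, %.3g]; rank correlation with degree %.3f\n",
              min(object$kappa), max(object$kappa),
              stats::cor(object$kappa, k, method = "spearman")))
  invisible(object)
}

#' @export
coef.ws1_fit <- function(object, ...) {
  c(beta = object$beta, mu = object$mu, nu = object$nu, tau = object$tau,
    a = object$a, eta = object$eta)
}

#' @export
logLik.ws1_fit <- function(object, ...) {
  structure(object$loglik, df = 2 * n_nodes(object$network) + 2,
            class = "logLik")
}

#' Simulate synthetic replicas from a WS1 fit
#'
#' Generates networks from the fitted model: S1 topology with the inferred
#' coordinates, hidden degrees, `beta` and `mu`; noiseless WS1 weights with
#' the inferred `sigma`, `tau` and `nu`.
#'
#' @param object A [ws1_fit()] object.
#' @param nsim Number of replicas.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of `wnet` replicas (a single `wnet` when `nsim = 1`... always
#'   a list, for predictability).
#' @export
simulate.ws1_fit <- function(object, nsim = 1, seed = 1L, ...) {
  n <- n_nodes(object$network)
  nodes <- data.frame(id = object$network$nodes$id, theta = object$theta,
                      kappa = object$kappa, sigma = object$sigma,
                      stringsAsFactors = FALSE)
  p <- ws1_params(n_nodes = n, beta = object$beta, mu = object$mu,
                  tau = object$tau, nu = object$nu,
                  kappa_law = kappa_values(object$kappa), seed = 1L)
  seeds <- derive_seeds(seed, nsim)
  lapply(seq_len(nsim), function(q) {
    net <- generate_topology(nodes, p, seed = seeds[q])
    assign_weights(net, p, seed = seeds[q])
  })
}

#' @export
plot.ws1_fit <- function(x, ...) {
  op <- graphics::par(mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  rad <- log(max(x$kappa) / x$kappa + 1)
  graphics::plot(rad * cos(x$theta), rad * sin(x$theta),
                 pch = 19, cex = 0.5, col = "steelblue",
                 xlab = "", ylab = "", axes = FALSE, asp = 1,
                 main = "Inferred similarity-space map", ...)
  invisible(x)
}
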