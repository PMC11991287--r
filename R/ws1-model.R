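#' WS1 model parameters
#'
#' Bundles the parameters of the weighted geometric soft configuration model
#' (WS1). Topology follows the S1 model: nodes live on a circle of radius
#' `R = N / (2 pi)` with hidden degrees `kappa`, and a pair is linked with the
#' gravity-law probability `p = 1 / (1 + chi^beta)` where
#' `chi = d / (mu kappa_i kappa_j)` and `d` is the arc distance. Weights on
#' existing links are `w = eps * nu * sigma_i sigma_j / ((kappa_i kappa_j)^(1 - tau) * d^tau)`
#' with hidden strengths `sigma = a * kappa^eta`.
#'
#' @param n_nodes Number of nodes.
#' @param beta Clustering/coupling parameter, must exceed 1.
#' @param mu Average-degree control; `NULL` means calibrate against
#'   `mean_degree` (see [calibrate_mu()]).
#' @param tau Coupling of weights to the metric space, in `[0, 1)`; 0 makes
#'   weights independent of geometry.
#' @param nu Global weight scale; `NULL` means calibrate so that the mean
#'   strength matches the mean hidden strength (see [calibrate_nu()]).
#' @param a,eta Parameters of the deterministic hidden-strength relation
#'   `sigma = a * kappa^eta`; `eta` slightly below 1 mimics the sublinear
#'   strength-degree relation of structural connectomes.
#' @param kappa_law Hidden-degree distribution: either [kappa_power_law()]
#'   (truncated power law) or [kappa_values()] (an explicit list, so empirical
#'   degree sequences can be injected).
#' @param mean_degree Target mean degree used when `mu` is `NULL`.
#' @param noise_model `"noiseless"` (multiplicative noise `eps` identically 1,
#'   the default) or `list(type = "gamma", shape = ...)` for unit-mean gamma
#'   noise.
#' @param seed Integer seed making every sampling step reproducible.
#' @return A list of class `ws1_params`.
#' @examples
#' p <- ws1_params(n_nodes = 500, beta = 2.5, tau = 0.5, seed = 7)
#' net <- sample_ws1(p)
#' summary(net)
#' @export
ws1_params <- function(n_nodes = 2000L, beta = 2.5, mu = NULL, tau = 0.5,
                       nu = NULL, a = 1, eta = 0.9,
                       kappa_law = kappa_power_law(),
                       mean_degree = 25, noise_model = "noiseless",
                       seed = 1L) {
  p <- list(n_nodes = as.integer(n_nodes), beta = beta, mu = mu, tau = tau,
            nu = nu, a = a, eta = eta, kappa_law = kappa_law,
            mean_degree = mean_degree, noise_model = noise_model,
            seed = as.integer(seed))
  validate_ws1_params(p)
  structure(p, class = "ws1_params")
}

validate_ws1_params <- function(p) {
  if (p$n_nodes < 2L) stop("n_nodes must be at least 2")
  if (!is.finite(p$beta) || p$beta <= 1) stop("beta must be > 1")
  if (!is.finite(p$tau) || p$tau < 0 || p$tau >= 1) stop("tau must lie in [0, 1)")
  for (nm in c("a", "eta", "mean_degree")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) stop(nm, " must be strictly positive")
  }
  if (!is.null(p$mu) && (!is.finite(p$mu) || p$mu <= 0)) stop("mu must be strictly positive")
  if (!is.null(p$nu) && (!is.finite(p$nu) || p$nu <= 0)) stop("nu must be strictly positive")
  validate_kappa_law(p$kappa_law)
  if (!identical(p$noise_model, "noiseless")) {
    if (!is.list(p$noise_model) || !identical(p$noise_model$type, "gamma") ||
        !is.numeric(p$noise_model$shape) || p$noise_model$shape <= 0) {
      stop("noise_model must be \"noiseless\" or list(type = \"gamma\", shape = <positive>)")
    }
  }
  invisible(p)
}

#' Hidden-degree laws
#'
#' `kappa_power_law()` specifies a power law with density proportional to
#' `kappa^-gamma` truncated to `[kappa_min, kappa_max]`; the defaults give the
#' heavy-tailed but cutoff degree distributions typical of structural
#' connectomes. `kappa_values()` injects an explicit list of hidden degrees
#' (e.g. observed degrees used as proxies), resampled with replacement if the
#' requested node count differs.
#'
#' @param gamma Power-law exponent (> 1).
#' @param kappa_min,kappa_max Truncation bounds, `0 < kappa_min < kappa_max`;
#'   `kappa_max = NULL` (the default) uses the natural cutoff
#'   `kappa_min * n^(1/(gamma-1))` of a scale-free ensemble of `n` nodes,
#'   resolved when nodes are sampled.
#' @param values Positive numeric vector of hidden degrees.
#' @return A kappa-law specification list.
#' @export
kappa_power_law <- function(gamma = 2.7, kappa_min = 4, kappa_max = NULL) {
  structure(list(type = "power", gamma = gamma, kappa_min = kappa_min,
                 kappa_max = kappa_max), class = "kappa_law")
}

#' @rdname kappa_power_law
#' @export
kappa_values <- function(values) {
  structure(list(type = "list", values = as.numeric(values)), class = "kappa_law")
}

validate_kappa_law <- function(law) {
  if (!is.list(law) || is.null(law$type)) stop("invalid kappa_law specification")
  if (law$type == "power") {
    if (!is.finite(law$gamma) || law$gamma <= 1) stop("kappa_law: gamma must be > 1")
    if (!(law$kappa_min > 0) ||
        (!is.null(law$kappa_max) && !(law$kappa_max > law$kappa_min)))
      stop("kappa_law: need 0 < kappa_min < kappa_max")
  } else if (law$type == "list") {
    if (!length(law$values) || any(!is.finite(law$values)) || any(law$values <= 0))
      stop("kappa_law: explicit values must be positive and finite")
  } else {
    stop("kappa_law: unknown type '", law$type, "'")
  }
  invisible(law)
}

# Fill in the natural cutoff kappa_min * n^(1/(gamma-1)) when kappa_max is
# left unspecified.
resolve_kappa_law <- function(law, n) {
  if (law$type == "power" && is.null(law$kappa_max)) {
    law$kappa_max <- law$kappa_min * n^(1 / (law$gamma - 1))
  }
  law
}

# Inverse-CDF sampling from the truncated power law.
sample_kappa <- function(n, law) {
  if (law$type == "list") {
    v <- law$values
    if (length(v) == n) return(v)
    return(sample(v, n, replace = TRUE))
  }
  law <- resolve_kappa_law(law, n)
  g <- law$gamma
  u <- runif(n)
  (law$kappa_min^(1 - g) + u * (law$kappa_max^(1 - g) - law$kappa_min^(1 - g)))^(1 / (1 - g))
}

# Closed-form mean of the truncated power law (used by tests as an oracle).
kappa_law_mean <- function(law) {
  if (law$type == "list") return(mean(law$values))
  g <- law$gamma; lo <- law$kappa_min; hi <- law$kappa_max
  norm <- (hi^(1 - g) - lo^(1 - g)) / (1 - g)
  if (abs(g - 2) < 1e-12) return(log(hi / lo) / norm)
  ((hi^(2 - g) - lo^(2 - g)) / (2 - g)) / norm
}

#' Sample node coordinates and hidden variables
#'
#' Draws angular positions uniformly on the circle (with a machine-scale
#' jitter so that no two angles coincide exactly, which would make the
#' geometry-coupled weight diverge), hidden degrees from the configured law,
#' hidden strengths `sigma = a * kappa^eta`, plus synthetic anatomy-style
#' metadata: hemisphere labels by angular half, and 3D Euclidean positions on
#' a jittered circle of brain-like radius (mm) that serve as per-edge length
#' proxies in cohorts.
#'
#' @param params A [ws1_params()] object.
#' @param seed Seed; defaults to `params$seed`.
#' @return Node data frame with columns `id`, `theta`, `kappa`, `sigma`,
#'   `x`, `y`, `z`, `hemisphere`.
#' @export
sample_ws1_nodes <- function(params, seed = params$seed) {
  validate_ws1_params(params)
  n <- params$n_nodes
  with_seed(seed, {
    theta <- runif(n, 0, 2 * pi)
    theta <- (theta + runif(n, -1e-12, 1e-12)) %% (2 * pi)
    kappa <- sample_kappa(n, params$kappa_law)
    sigma <- params$a * kappa^params$eta
    rho <- 70  # mm, cortical-shell scale
    x <- rho * cos(theta) + rnorm(n, 0, 8)
    y <- rho * sin(theta) + rnorm(n, 0, 8)
    z <- rnorm(n, 0, 8)
    data.frame(id = sprintf("n%04d", seq_len(n)), theta = theta, kappa = kappa,
               sigma = sigma, x = x, y = y, z = z,
               hemisphere = ifelse(theta < pi, "L", "R"),
               stringsAsFactors = FALSE)
  })
}

#' S1 gravity-law connection probability
#'
#' `p = 1 / (1 + chi^beta)` with `chi = d / (mu kappa_i kappa_j)` and
#' `d = R * dtheta` the shorter-arc distance on the circle of radius
#' `R = n_nodes / (2 pi)`. Strictly decreasing in distance, strictly
#' increasing in the product of hidden degrees; `p = 1/2` at `chi = 1` and
#' `p = 1` at zero distance.
#'
#' @param theta_i,theta_j Angular positions (radians), vectorized.
#' @param kappa_i,kappa_j Hidden degrees (> 0).
#' @param params A [ws1_params()] with non-`NULL` `mu`.
#' @return Probabilities in `[0, 1]`.
#' @export
connection_probability <- function(theta_i, theta_j, kappa_i, kappa_j, params) {
  if (any(kappa_i <= 0) || any(kappa_j <= 0)) stop("hidden degrees must be > 0")
  if (is.null(params$mu)) stop("params$mu is not set; calibrate it first")
  R <- params$n_nodes / (2 * pi)
  d <- R * delta_theta(theta_i, theta_j)
  chi <- d / (params$mu * kappa_i * kappa_j)
  1 / (1 + chi^params$beta)
}

#' Calibrate the average-degree parameter mu
#'
#' Finds `mu` such that the expected mean degree of the model over the given
#' node realization, `(2/N) * sum_{i<j} p_ij(mu)`, equals the target. The
#' closed form `beta * sin(pi/beta) / (2 pi <k>)` initializes a root search
#' that corrects for finite size and hidden-degree cutoffs. Deterministic
#' given the node set.
#'
#' @param params A [ws1_params()] object.
#' @param target_mean_degree Desired ensemble mean degree.
#' @param nodes Optional node table from [sample_ws1_nodes()]; sampled from
#'   `params` when omitted.
#' @return The calibrated `mu` (positive scalar).
#' @export
calibrate_mu <- function(params, target_mean_degree = params$mean_degree,
                         nodes = NULL) {
  validate_ws1_params(params)
  if (!is.finite(target_mean_degree) || target_mean_degree <= 0)
    stop("target_mean_degree must be positive")
  if (target_mean_degree >= params$n_nodes - 1)
    stop("target_mean_degree infeasible for n_nodes")
  if (is.null(nodes)) nodes <- sample_ws1_nodes(params)
  n <- nrow(nodes)
  R <- n / (2 * pi)
  pr <- pair_indices(n)
  chi0 <- R * delta_theta(nodes$theta[pr$i], nodes$theta[pr$j]) /
    (nodes$kappa[pr$i] * nodes$kappa[pr$j])
  beta <- params$beta
  f <- function(mu) 2 / n * sum(1 / (1 + (chi0 / mu)^beta)) - target_mean_degree
  mu0 <- beta * sin(pi / beta) / (2 * pi * target_mean_degree)
  sol <- tryCatch(
    uniroot(f, lower = mu0 / 100, upper = mu0 * 100, extendInt = "upX",
            tol = mu0 * 1e-9),
    error = function(e) stop("mu calibration failed to converge: ",
                             conditionMessage(e)))
  sol$root
}

#' Generate an S1 topology
#'
#' Links each unordered pair independently with [connection_probability()].
#' Edge weights are set to a placeholder of 1 until [assign_weights()] is
#' applied.
#'
#' @param nodes Node table from [sample_ws1_nodes()].
#' @param params A [ws1_params()] with `mu` set.
#' @param seed Seed for the Bernoulli draws.
#' @return A [weighted_network()] whose `nodes` table carries the latent
#'   coordinates.
#' @export
generate_topology <- function(nodes, params, seed = params$seed) {
  validate_ws1_params(params)
  if (is.null(params$mu)) stop("params$mu is not set; calibrate it first")
  n <- nrow(nodes)
  pr <- pair_indices(n)
  p <- connection_probability(nodes$theta[pr$i], nodes$theta[pr$j],
                              nodes$kappa[pr$i], nodes$kappa[pr$j], params)
  keep <- with_seed(seed, runif(length(p)) < p)
  weighted_network(data.frame(from = pr$i[keep], to = pr$j[keep],
                              weight = rep(1, sum(keep))),
                   nodes = nodes)
}

# Arc distances for the edges of a network whose node table has theta.
edge_arc_distances <- function(net) {
  n <- n_nodes(net)
  R <- n / (2 * pi)
  R * delta_theta(net$nodes$theta[net$edges$from], net$nodes$theta[net$edges$to])
}

#' Assign geometry-coupled weights
#'
#' Puts `w_ij = eps_ij * nu * sigma_i sigma_j / ((kappa_i kappa_j)^(1 - tau) * d_ij^tau)`
#' on every edge of the topology, with `eps` identically 1 in the noiseless
#' model.
#'
#' @param network A `wnet` whose node table carries `theta`, `kappa`, `sigma`.
#' @param params A [ws1_params()]; `nu = NULL` is treated as 1.
#' @param seed Seed, used only when the noise model is stochastic.
#' @return The network with weights replaced.
#' @export
assign_weights <- function(network, params, seed = params$seed) {
  validate_ws1_params(params)
  stopifnot(all(c("theta", "kappa", "sigma") %in% names(network$nodes)))
  d <- edge_arc_distances(network)
  if (params$tau > 0 && any(d <= 0))
    stop("coincident angular positions give zero distance; weights undefined for tau > 0")
  nu <- params$nu %||% 1
  e <- network$edges
  kp <- network$nodes$kappa[e$from] * network$nodes$kappa[e$to]
  sp <- network$nodes$sigma[e$from] * network$nodes$sigma[e$to]
  w <- nu * sp / (kp^(1 - params$tau) * d^params$tau)
  if (!identical(params$noise_model, "noiseless")) {
    sh <- params$noise_model$shape
    w <- w * with_seed(seed, rgamma(length(w), shape = sh, rate = sh))
  }
  e$weight <- w
  replace_edges(network, e)
}

#' Calibrate the weight-scale parameter nu
#'
#' Weights are linear in `nu`, so the value making the realized mean strength
#' equal the mean hidden strength, `<s> = <sigma>`, is obtained exactly from a
#' single evaluation at `nu = 1`.
#'
#' @param network A `wnet` with latent node coordinates (weights need not be
#'   assigned yet).
#' @param params A [ws1_params()].
#' @return The calibrated `nu`.
#' @export
calibrate_nu <- function(network, params) {
  if (n_edges(network) == 0L) stop("cannot calibrate nu on an empty edge set")
  p1 <- params
  p1$nu <- 1
  p1$noise_model <- "noiseless"
  unit <- assign_weights(network, p1)
  mean(network$nodes$sigma) / mean(node_strengths(unit))
}

#' Sample a complete WS1 network
#'
#' Convenience wrapper chaining [sample_ws1_nodes()], [calibrate_mu()] (when
#' `mu` is unset), [generate_topology()], [calibrate_nu()] (when `nu` is
#' unset) and [assign_weights()]. The realized `mu` and `nu` are recorded in
#' `attr(net, "params")`.
#'
#' @param params A [ws1_params()] object.
#' @param seed Master seed; defaults to `params$seed`.
#' @param nodes Optional pre-sampled node table (e.g. shared across a cohort).
#' @return A `wnet` with latent coordinates and WS1 weights.
#' @export
sample_ws1 <- function(params, seed = params$seed, nodes = NULL) {
  validate_ws1_params(params)
  seeds <- derive_seeds(seed, 3L)
  if (is.null(nodes)) nodes <- sample_ws1_nodes(params, seed = seeds[1])
  p <- params
  if (is.null(p$mu)) p$mu <- calibrate_mu(p, p$mean_degree, nodes = nodes)
  net <- generate_topology(nodes, p, seed = seeds[2])
  if (is.null(p$nu)) p$nu <- calibrate_nu(net, p)
  net <- assign_weights(net, p, seed = seeds[3])
  attr(net, "params") <- p
  net
}

#' Generate a multi-subject cohort
#'
#' All subjects share one node set (identities, angular positions, Euclidean
#' positions and hemisphere labels); each subject re-draws topology and
#' weights from the model after a small multiplicative lognormal jitter of the
#' hidden degrees, emulating subject-level fluctuation around a common
#' geometric backbone. Per-edge length proxies are the Euclidean distances
#' between the fixed node positions, hence identical across subjects.
#'
#' @param params A [ws1_params()] object.
#' @param n_subjects Number of subjects (>= 2).
#' @param subject_variability Standard deviation of the lognormal kappa
#'   jitter; 0 disables it.
#' @param seed Master seed.
#' @param subject_seeds Optional integer vector of per-subject seeds
#'   (recycled); by default distinct sub-seeds are derived from `seed`.
#' @return An object of class `ws1_cohort`: list with `nodes`, `subjects`
#'   (list of `wnet`) and `params`.
#' @export
generate_cohort <- function(params, n_subjects = 40L, subject_variability = 0.1,
                            seed = params$seed, subject_seeds = NULL) {
  validate_ws1_params(params)
  stopifnot(n_subjects >= 2L, subject_variability >= 0)
  seeds <- derive_seeds(seed, 1L + n_subjects)
  nodes <- sample_ws1_nodes(params, seed = seeds[1])
  if (is.null(subject_seeds)) {
    subject_seeds <- seeds[-1]
  } else {
    subject_seeds <- rep_len(as.integer(subject_seeds), n_subjects)
  }
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    nd <- nodes
    if (subject_variability > 0) {
      jit <- with_seed(subject_seeds[s] %% 999999937L + 1L,
                       rnorm(nrow(nd), 0, subject_variability))
      nd$kappa <- nd$kappa * exp(jit - subject_variability^2 / 2)
      nd$sigma <- params$a * nd$kappa^params$eta
    }
    subjects[[s]] <- sample_ws1(params, seed = subject_seeds[s], nodes = nd)
  }
  structure(list(nodes = nodes, subjects = subjects, params = params),
            class = "ws1_cohort")
}

#' @export
print.ws1_cohort <- function(x, ...) {
  cat(sprintf("WS1 cohort: %d subjects over %d shared nodes\n",
              length(x$subjects), nrow(x$nodes)))
  invisible(x)
}

#' @export
print.ws1_params <- function(x, ...) {
  cat("WS1 model parameters\n")
  cat(sprintf("  n_nodes = %d, beta = %.3g, tau = %.3g, eta = %.3g, a = %.3g\n",
              x$n_nodes, x$beta, x$tau, x$eta, x$a))
  cat(sprintf("  mu = %s, nu = %s, target <k> = %.3g\n",
              if (is.null(x$mu)) "(calibrate)" else format(x$mu, digits = 4),
              if (is.null(x$nu)) "(calibrate)" else format(x$nu, digits = 4),
              x$mean_degree))
  if (x$kappa_law$type == "power") {
    cat(sprintf("  kappa ~ power law gamma = %.3g on [%.3g, %s]\n",
                x$kappa_law$gamma, x$kappa_law$kappa_min,
                if (is.null(x$kappa_law$kappa_max)) "natural cutoff"
                else format(x$kappa_law$kappa_max, digits = 3)))
  } else {
    cat(sprintf("  kappa: explicit list of %d values\n", length(x$kappa_law$values)))
  }
  invisible(x)
}
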