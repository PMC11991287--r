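# Weighted observables: complementary cumulative distributions, the
# strength-degree relation and its exponent, the disparity profile with its
# analytic random-null band, and layer-wise rescaling.

#' Complementary cumulative distribution
#'
#' `P_c(v) = P(X >= v)` evaluated at every observed value, so that
#' `P_c(min) = 1` exactly and the curve is monotone non-increasing. Used for
#' the weight, strength and degree distributions of each layer.
#'
#' @param values Non-empty vector of positive values.
#' @return Data frame with columns `value` and `ccdf`.
#' @examples
#' ccdf(c(1, 2, 3))  # P_c = 1, 2/3, 1/3
#' @export
ccdf <- function(values) {
  if (!length(values)) stop("ccdf of an empty sample is undefined")
  stopifnot(all(is.finite(values)))
  srt <- sort(values)
  v <- unique(srt)
  n_less <- findInterval(v, srt, left.open = TRUE)
  data.frame(value = v, ccdf = (length(srt) - n_less) / length(srt))
}

#' Log-binned curve
#'
#' Averages `y` within geometric (log-spaced) bins of positive `x`; only
#' occupied bins are reported. This is the binning used for reporting
#' strength-degree and disparity profiles (30 bins by default).
#'
#' @param x,y Numeric vectors of equal length, `x > 0`.
#' @param n_bins Number of geometric bins.
#' @return Data frame with `x` (geometric bin center), `mean`, `sd`, `n`.
#' @export
binned_curve <- function(x, y, n_bins = 30) {
  stopifnot(length(x) == length(y), all(x > 0))
  edges <- log_bin_edges(x, n_bins)
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  keep <- sort(unique(bin))
  data.frame(
    x = sqrt(edges[keep] * edges[keep + 1L]),
    mean = vapply(keep, function(b) mean(y[bin == b]), numeric(1)),
    sd = vapply(keep, function(b) if (sum(bin == b) > 1) sd(y[bin == b]) else 0,
                numeric(1)),
    n = vapply(keep, function(b) sum(bin == b), numeric(1)))
}

#' Strength-degree relation and its exponent
#'
#' Computes the average strength for nodes in each degree class, then fits
#' `s(k) ~ a * k^eta` by unweighted least squares on log-binned degree
#' classes (geometric bins, only bins holding at least `min_nodes` nodes).
#' When fewer than two usable bins exist the fit falls back to the raw degree
#' classes; with a single degree class the exponent is undefined and flagged.
#'
#' @param network A `wnet`.
#' @param n_bins Number of geometric degree bins for the fit.
#' @param min_nodes Minimum nodes per bin for the bin to enter the fit.
#' @return List with `curve` (data frame `k`, `s_mean`, `n_nodes`), `eta`,
#'   `a`, and `eta_defined`.
#' @export
strength_degree_profile <- function(network, n_bins = 30, min_nodes = 3) {
  k <- node_degrees(network)
  s <- node_strengths(network)
  keep <- k > 0
  k <- k[keep]; s <- s[keep]
  if (!length(k)) stop("network has no connected nodes")
  ks <- sort(unique(k))
  s_mean <- vapply(ks, function(d) mean(s[k == d]), numeric(1))
  n_k <- vapply(ks, function(d) sum(k == d), numeric(1))
  curve <- data.frame(k = ks, s_mean = s_mean, n_nodes = n_k)
  if (length(ks) < 2L) {
    return(list(curve = curve, eta = NA_real_, a = NA_real_, eta_defined = FALSE))
  }
  edges <- log_bin_edges(ks, min(n_bins, length(ks)))
  bin <- findInterval(ks, edges, rightmost.closed = TRUE, all.inside = TRUE)
  bx <- tapply(log10(ks), bin, mean)
  by <- tapply(log10(s_mean), bin, mean)
  bn <- tapply(n_k, bin, sum)
  use <- bn >= min_nodes
  if (sum(use) < 2L) {
    fit <- lm(log10(s_mean) ~ log10(ks))
  } else {
    fit <- lm(by[use] ~ bx[use])
  }
  co <- coef(fit)
  list(curve = curve, eta = unname(co[2]), a = 10^unname(co[1]),
       eta_defined = TRUE)
}

#' Node-level disparity
#'
#' `Upsilon(k_i) = k_i * sum_j (w_ij / s_i)^2`, the local heterogeneity of
#' the weights attached to a node: 1 when the strength is spread evenly over
#' the `k_i` links, `k_i` when a single link carries everything. Isolated
#' nodes are excluded.
#'
#' @param network A `wnet`.
#' @return Data frame with one row per connected node: `node`, `k`,
#'   `upsilon`.
#' @export
disparity <- function(network) {
  k <- node_degrees(network)
  s <- node_strengths(network)
  e <- network$edges
  frac2 <- (e$weight / s[e$from])^2
  frac2b <- (e$weight / s[e$to])^2
  y <- numeric(n_nodes(network))
  add <- rowsum(c(frac2, frac2b), group = c(e$from, e$to))
  y[as.integer(rownames(add))] <- add[, 1L]
  keep <- which(k > 0)
  data.frame(node = keep, k = k[keep], upsilon = k[keep] * y[keep])
}

#' Disparity profile by degree class
#'
#' Average disparity per degree class, with the analytic expectation and
#' upper bound of the locally-uniform random null attached (see
#' [disparity_null_band()]).
#'
#' @param network A `wnet`.
#' @param upsilon Width multiplier of the null band.
#' @return Data frame with `k`, `upsilon_mean`, `n_nodes`, `E_random`,
#'   `V_random`, `upper`.
#' @export
disparity_profile <- function(network, upsilon = 2) {
  d <- disparity(network)
  ks <- sort(unique(d$k))
  um <- vapply(ks, function(q) mean(d$upsilon[d$k == q]), numeric(1))
  nn <- vapply(ks, function(q) sum(d$k == q), numeric(1))
  band <- disparity_null_band(ks, upsilon = upsilon)
  data.frame(k = ks, upsilon_mean = um, n_nodes = nn,
             E_random = band$E_random, V_random = band$V_random,
             upper = band$upper)
}

#' Analytic disparity null band
#'
#' For a node of degree `k` whose normalized weights follow the null of a
#' locally uniform random split of the strength (k-1 uniform points dropped
#' on \[0,1\], subinterval lengths as weights), the disparity has expectation
#' `E(k) = 2k / (k + 1)` and variance
#' `V(k) = k^2 * ((20 + 4k) / ((k+1)(k+2)(k+3)) - 4 / (k+1)^2)`.
#' A node is compatible with the null when `Upsilon(k) < E(k) + upsilon * V(k)`
#' with `upsilon = 2`.
#'
#' @param k Integer degree(s), `>= 1`.
#' @param upsilon Band width multiplier (default 2).
#' @return Data frame with `k`, `E_random`, `V_random`, `upper`.
#' @export
disparity_null_band <- function(k, upsilon = 2) {
  if (any(k < 1)) stop("degree must be at least 1")
  k <- as.numeric(k)
  E <- 2 * k / (k + 1)
  V <- k^2 * ((20 + 4 * k) / ((k + 1) * (k + 2) * (k + 3)) - 4 / (k + 1)^2)
  data.frame(k = k, E_random = E, V_random = V, upper = E + upsilon * V)
}

#' Rescale a layer by its averages
#'
#' Divides weights, strengths and degrees by the layer averages so that each
#' rescaled sequence has mean exactly 1; this is the normalization under
#' which distributions of different renormalization layers are compared.
#'
#' @param network A `wnet`.
#' @return List with numeric vectors `weight`, `strength`, `degree`.
#' @export
layer_rescale <- function(network) {
  stopifnot(n_edges(network) > 0L)
  w <- network$edges$weight
  s <- node_strengths(network)
  k <- node_degrees(network)
  list(weight = w / mean(w), strength = s / mean(s), degree = k / mean(k))
}
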