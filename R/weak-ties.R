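# Module detection, the two weight filters, the disparity-filter confidence,
# the weak-ties spectrum and intra/inter-modular weight comparison.

#' Louvain module detection
#'
#' Community detection with the Louvain algorithm (resolution 1). In
#' `"unweighted"` mode all edge weights are ignored so that the partition is
#' not directly influenced by the weights under study; `"weighted"` mode uses
#' the weights. Deterministic given the seed; disconnected components are
#' handled independently by the algorithm.
#'
#' @param network A non-empty `wnet`.
#' @param mode `"unweighted"` (default) or `"weighted"`.
#' @param seed Integer seed fixing the algorithm's randomized vertex order.
#' @return Integer vector of module ids (one per node), named by node id.
#' @export
detect_modules <- function(network, mode = c("unweighted", "weighted"),
                           seed = 1L) {
  mode <- match.arg(mode)
  if (n_edges(network) == 0L) stop("cannot detect modules in an empty network")
  g <- as_igraph(network)
  w <- if (mode == "unweighted") NA else igraph::E(g)$weight
  cl <- with_seed(seed, igraph::cluster_louvain(g, weights = w))
  setNames(as.integer(igraph::membership(cl)), network$nodes$id)
}

# Shared filter machinery: rank edges by (key, canonical index), keep the
# lowest ceiling(percent/100 * E). The prefix structure makes filters nested.
filter_by_rank <- function(network, key, percent) {
  if (!is.finite(percent) || percent <= 0 || percent > 100)
    stop("percent must lie in (0, 100]")
  m <- n_edges(network)
  keep_n <- ceiling(percent / 100 * m)
  ord <- order(key, seq_len(m))
  keep <- sort(ord[seq_len(keep_n)])
  replace_edges(network, network$edges[keep, , drop = FALSE])
}

#' Global weight filter
#'
#' Ranks all connections by weight from lowest to highest and keeps the
#' `percent`% with the lowest weight (ties broken by canonical edge index, so
#' the retained count is reproducible). Nodes are unchanged.
#'
#' @param network A `wnet`.
#' @param percent Percentage of edges to retain, in `(0, 100]`.
#' @return The filtered `wnet`.
#' @export
global_weight_filter <- function(network, percent) {
  filter_by_rank(network, network$edges$weight, percent)
}

#' Disparity-filter confidence of edges
#'
#' For each edge endpoint of degree `k >= 2`, the probability that the
#' normalized weight `w/s` is compatible with a locally uniform random split
#' of the node's strength is
#' `alpha = 1 - (k - 1) * integral_0^{w/s} (1 - x)^(k-2) dx = (1 - w/s)^(k-1)`.
#' An undirected edge carries one alpha per endpoint; the edge-level value is
#' the minimum of the two (the maximum confidence), the conservative
#' convention of the disparity-filter literature. Degree-1 endpoints give
#' `alpha = 1` (never significant). The confidence is `1 - alpha`.
#'
#' @param network A `wnet`.
#' @return Data frame with one row per edge: `from`, `to`, `weight`,
#'   `alpha_from`, `alpha_to`, `alpha`, `confidence`.
#' @export
edge_confidence <- function(network) {
  k <- node_degrees(network)
  s <- node_strengths(network)
  e <- network$edges
  alpha_end <- function(nodes) {
    kk <- k[nodes]
    frac <- e$weight / s[nodes]
    if (any(frac > 1 + 1e-12))
      stop("edge weight exceeds endpoint strength; corrupted strengths")
    frac <- pmin(frac, 1)
    ifelse(kk >= 2, (1 - frac)^(kk - 1), 1)
  }
  a_from <- alpha_end(e$from)
  a_to <- alpha_end(e$to)
  a <- pmin(a_from, a_to)
  data.frame(from = e$from, to = e$to, weight = e$weight,
             alpha_from = a_from, alpha_to = a_to,
             alpha = a, confidence = 1 - a)
}

#' Confidence filter
#'
#' Keeps the `percent`% of edges with the lowest disparity-filter confidence
#' (see [edge_confidence()]); the analogue of [global_weight_filter()] with
#' weight replaced by statistical significance.
#'
#' @inheritParams global_weight_filter
#' @return The filtered `wnet`.
#' @export
confidence_filter <- function(network, percent) {
  conf <- edge_confidence(network)$confidence
  filter_by_rank(network, conf, percent)
}

#' Density of intermodular connections
#'
#' Ratio between the number of links connecting nodes in different modules
#' and the total number of links.
#'
#' @param network A `wnet` (possibly filtered).
#' @param partition Module assignment over (at least) the network's nodes,
#'   as returned by [detect_modules()].
#' @return A number in `[0, 1]`, or `NA` (with a warning) when the network
#'   has no edges.
#' @export
intermodular_density <- function(network, partition) {
  stopifnot(length(partition) >= n_nodes(network))
  if (n_edges(network) == 0L) {
    warning("no edges after filtering; intermodular density undefined")
    return(NA_real_)
  }
  mean(partition[network$edges$from] != partition[network$edges$to])
}

#' Weak-ties spectrum
#'
#' Normalized density of intermodular connections
#' `rho_inter(n) = RE_n / RE_100` as a function of the percentage `n` of
#' retained edges, filtering either by weight or by confidence. The partition
#' is computed on the unfiltered network and held fixed; `rho_inter(100) = 1`
#' by construction. When the partition has a single module there are no
#' intermodular links and the spectrum is flagged undefined.
#'
#' @param network A `wnet`.
#' @param partition Module assignment from [detect_modules()] on the
#'   unfiltered network.
#' @param filter `"weight"` or `"confidence"`.
#' @param percents Percentages to evaluate; 100 is added if absent.
#' @return List of class `weak_ties_spectrum`: `percents`, `RE`, `rho`,
#'   `defined`, `filter`.
#' @export
weak_ties_spectrum <- function(network, partition,
                               filter = c("weight", "confidence"),
                               percents = c(1, 2, 5, 10, 20, 50, 100)) {
  filter <- match.arg(filter)
  percents <- sort(unique(c(percents, 100)))
  key <- if (filter == "weight") network$edges$weight
         else edge_confidence(network)$confidence
  m <- n_edges(network)
  ord <- order(key, seq_len(m))
  inter <- (partition[network$edges$from] != partition[network$edges$to])[ord]
  cum_inter <- cumsum(inter)
  keep_n <- pmax(1L, ceiling(percents / 100 * m))
  RE <- unname(cum_inter[keep_n]) / keep_n
  RE100 <- RE[length(RE)]
  defined <- RE100 > 0
  if (!defined) {
    warning("single-module partition: no intermodular links, spectrum undefined")
  }
  structure(list(percents = percents, RE = RE,
                 rho = if (defined) RE / RE100 else rep(NA_real_, length(RE)),
                 defined = defined, filter = filter),
            class = "weak_ties_spectrum")
}

#' @export
print.weak_ties_spectrum <- function(x, ...) {
  cat(sprintf("Weak-ties spectrum (%s filter)%s\n", x$filter,
              if (x$defined) "" else " -- undefined (single module)"))
  print(data.frame(percent = x$percents, RE = x$RE, rho_inter = x$rho),
        row.names = FALSE)
  invisible(x)
}

#' Intra- versus inter-modular mean weights
#'
#' The intramodular value is the unweighted mean, over modules with at least
#' one internal edge, of each module's mean edge weight; the intermodular
#' value is the mean weight over all edges joining different modules.
#'
#' @param network A `wnet`.
#' @param partition Module assignment covering the network's nodes, with at
#'   least two modules.
#' @return Named numeric vector `c(intra = ..., inter = ...)`; `inter` is
#'   `NA` if no intermodular edge exists.
#' @export
intra_inter_mean_weights <- function(network, partition) {
  if (length(unique(partition[seq_len(n_nodes(network))])) < 2L)
    stop("partition has a single module; intra/inter comparison undefined")
  e <- network$edges
  mod_from <- partition[e$from]
  mod_to <- partition[e$to]
  intra <- mod_from == mod_to
  if (!any(intra)) stop("no module has an internal edge")
  per_module <- tapply(e$weight[intra], mod_from[intra], mean)
  empty <- setdiff(as.character(unique(partition)), names(per_module))
  if (length(empty))
    message(length(empty), " module(s) without internal edges excluded from the intra mean")
  c(intra = mean(per_module),
    inter = if (any(!intra)) mean(e$weight[!intra]) else NA_real_)
}
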