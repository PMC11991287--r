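# sup-GRW: geometric renormalization of weighted networks. Nodes are grouped
# into blocks of r angularly consecutive nodes; two supernodes are linked iff
# some pair of constituents is linked, with the supremum of the constituent
# weights; the flow iterates the step.

#' Angular coarse-graining blocks
#'
#' Orders nodes by angular position (ties broken by node index, so the block
#' structure is independent of the input ordering) and delimits consecutive
#' non-overlapping sectors of `r` nodes each; the last block keeps the
#' remainder when `r` does not divide the node count.
#'
#' @param nodes Node data frame with a `theta` column.
#' @param r Block resolution (>= 2 nodes per block).
#' @return List of class `block_map`: `block` (block id per node, in input
#'   order), `n_blocks`, `r`.
#' @export
angular_blocks <- function(nodes, r) {
  stopifnot(is.data.frame(nodes))
  if (!("theta" %in% names(nodes)) || any(!is.finite(nodes$theta)))
    stop("angular positions (theta) must be defined for all nodes")
  r <- as.integer(r)
  if (r < 2L) stop("resolution r must be at least 2")
  n <- nrow(nodes)
  ord <- order(nodes$theta, seq_len(n))
  block <- integer(n)
  block[ord] <- (seq_len(n) - 1L) %/% r + 1L
  structure(list(block = block, n_blocks = max(block), r = r),
            class = "block_map")
}

#' One sup-GRW renormalization step
#'
#' Coarse-grains the network over a [angular_blocks()] map: supernodes are
#' the blocks; two supernodes are connected iff at least one edge joins their
#' constituents, with weight the supremum of those edge weights;
#' intra-block edges are absorbed. The supernode angular position is the
#' arithmetic mean of the constituent angles (blocks are consecutive arcs, so
#' the mean lies inside the block's sector); its hidden degree follows the
#' standard geometric-renormalization rule `kappa' = (sum kappa^beta)^(1/beta)`
#' when `beta` is available.
#'
#' @param network A `wnet` whose node table has `theta` (and optionally
#'   `kappa`, positions and hemisphere labels, which are aggregated).
#' @param block_map A `block_map`; computed from the node table when omitted.
#' @param r Resolution used when `block_map` is omitted.
#' @param beta Coupling exponent for the hidden-degree aggregation; taken
#'   from `attr(network, "params")` when available.
#' @param id_prefix Prefix for supernode ids.
#' @return List with `network` (the coarse `wnet`) and `map` (integer
#'   node-to-supernode vector).
#' @export
renormalize_step <- function(network, block_map = NULL, r = 2,
                             beta = NULL, id_prefix = "sn") {
  stopifnot(inherits(network, "wnet"))
  if (is.null(block_map)) block_map <- angular_blocks(network$nodes, r)
  stopifnot(inherits(block_map, "block_map"),
            length(block_map$block) == n_nodes(network))
  if (is.null(beta)) beta <- attr(network, "params")$beta
  b <- block_map$block
  B <- block_map$n_blocks

  nd <- network$nodes
  fb <- factor(b, levels = seq_len(B))  # numeric level order, not lexicographic
  agg <- function(x, f) as.vector(tapply(x, fb, f))
  coarse_nodes <- data.frame(id = sprintf("%s%04d", id_prefix, seq_len(B)),
                             theta = agg(nd$theta, mean),
                             stringsAsFactors = FALSE)
  if ("kappa" %in% names(nd) && !is.null(beta)) {
    coarse_nodes$kappa <- agg(nd$kappa, function(v) sum(v^beta)^(1 / beta))
  }
  for (col in c("x", "y", "z")) {
    if (col %in% names(nd)) coarse_nodes[[col]] <- agg(nd[[col]], mean)
  }
  if ("hemisphere" %in% names(nd)) {
    coarse_nodes$hemisphere <- agg(nd$hemisphere, function(v)
      names(sort(table(v), decreasing = TRUE))[1])
  }

  e <- network$edges
  bi <- pmin(b[e$from], b[e$to])
  bj <- pmax(b[e$from], b[e$to])
  keep <- bi != bj
  if (any(keep)) {
    key <- (bi[keep] - 1) * B + bj[keep]
    sup <- tapply(e$weight[keep], key, max)
    kfirst <- as.numeric(names(sup))
    coarse_edges <- data.frame(from = as.integer((kfirst - 1) %/% B + 1),
                               to = as.integer((kfirst - 1) %% B + 1),
                               weight = as.vector(sup))
  } else {
    coarse_edges <- data.frame(from = integer(0), to = integer(0),
                               weight = numeric(0))
  }
  coarse <- structure(list(nodes = coarse_nodes, edges = coarse_edges),
                      class = "wnet")
  coarse <- replace_edges(coarse, coarse_edges)
  attr(coarse, "params") <- attr(network, "params")
  list(network = coarse, map = b)
}

#' Iterated sup-GRW flow
#'
#' Applies [renormalize_step()] `n_steps` times with fixed resolution `r`,
#' producing a multiscale unfolding of `n_steps + 1` layers (layer 0 is the
#' input) with `N_{l+1} = ceiling(N_l / r)`. The transformation has semigroup
#' structure: two steps at resolution `r` coincide exactly with one step at
#' `r^2`.
#'
#' @inheritParams renormalize_step
#' @param r Block resolution.
#' @param n_steps Number of steps; must not exceed `log_r` of the node count.
#' @return Object of class `layer_stack`: list with `layers` (list of
#'   `wnet`, index `l + 1`), `maps` (node-to-supernode integer vectors
#'   between consecutive layers) and `r`.
#' @export
renormalize_flow <- function(network, r = 2, n_steps, beta = NULL) {
  stopifnot(inherits(network, "wnet"), n_steps >= 1)
  if (n_steps > log(n_nodes(network)) / log(r) + 1e-9)
    stop("n_steps exceeds log_r of the node count")
  layers <- vector("list", n_steps + 1L)
  maps <- vector("list", n_steps)
  layers[[1L]] <- network
  cur <- network
  for (l in seq_len(n_steps)) {
    step <- renormalize_step(cur, r = r, beta = beta,
                             id_prefix = sprintf("l%d_", l))
    layers[[l + 1L]] <- step$network
    maps[[l]] <- step$map
    cur <- step$network
  }
  structure(list(layers = layers, maps = maps, r = r), class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("Layer stack (r = %s): %d layers\n", format(x$r), length(x$layers)))
  for (l in seq_along(x$layers)) {
    net <- x$layers[[l]]
    cat(sprintf("  l = %d: %d nodes, %d edges, <k> = %.2f, <w> = %.4g\n",
                l - 1L, n_nodes(net), n_edges(net),
                mean(node_degrees(net)),
                if (n_edges(net)) mean(net$edges$weight) else NA_real_))
  }
  invisible(x)
}
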