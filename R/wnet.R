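#' Undirected weighted network container
#'
#' Builds the package's basic container for an undirected simple graph with
#' strictly positive edge weights. Node identifiers are opaque strings; edges
#' are stored with contiguous integer endpoint indices canonicalized so that
#' `from < to`, which makes undirected uniqueness checks and multi-edge
#' detection trivial.
#'
#' @param edges Data frame with columns `from`, `to` (node ids or integer
#'   indices) and `weight` (positive numbers).
#' @param nodes Optional data frame with at least a character column `id`;
#'   further columns (`theta`, `kappa`, `sigma`, `x`, `y`, `z`, `hemisphere`)
#'   carry latent coordinates and anatomy-style metadata. When omitted, the
#'   node table is derived from the edge list.
#' @return An object of class `wnet`: a list with elements `nodes` (data
#'   frame) and `edges` (data frame of integer `from`, `to` and numeric
#'   `weight`).
#' @examples
#' net <- weighted_network(data.frame(from = c("a", "a"), to = c("b", "c"),
#'                                    weight = c(1, 2)))
#' net
#' @export
weighted_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to", "weight") %in% names(edges)))
  if (is.null(nodes)) {
    ids <- sort(unique(c(as.character(edges$from), as.character(edges$to))))
    nodes <- data.frame(id = ids, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(nodes), "id" %in% names(nodes))
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicated node ids")

  if (is.character(edges$from) || is.factor(edges$from)) {
    from <- match(as.character(edges$from), nodes$id)
    to <- match(as.character(edges$to), nodes$id)
    if (anyNA(from) || anyNA(to)) stop("edge endpoint not present in node table")
  } else {
    from <- as.integer(edges$from)
    to <- as.integer(edges$to)
    if (length(from) && (min(c(from, to)) < 1L || max(c(from, to)) > nrow(nodes)))
      stop("edge endpoint index out of range")
  }
  w <- as.numeric(edges$weight)
  if (any(!is.finite(w)) || any(w <= 0)) stop("edge weights must be strictly positive")
  if (any(from == to)) stop("self-loops are not allowed")

  lo <- pmin(from, to)
  hi <- pmax(from, to)
  o <- order(lo, hi)
  lo <- lo[o]; hi <- hi[o]; w <- w[o]
  if (length(lo) > 1L && any(lo[-1L] == lo[-length(lo)] & hi[-1L] == hi[-length(hi)]))
    stop("duplicated undirected edge (multi-edge)")

  structure(list(nodes = nodes,
                 edges = data.frame(from = lo, to = hi, weight = w)),
            class = "wnet")
}

n_nodes <- function(net) nrow(net$nodes)
n_edges <- function(net) nrow(net$edges)

#' Node degrees and strengths
#'
#' @param net A `wnet` object.
#' @return Integer vector of degrees, or numeric vector of strengths
#'   (sum of incident edge weights), aligned with `net$nodes`.
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "wnet"))
  tabulate(c(net$edges$from, net$edges$to), nbins = n_nodes(net))
}

#' @rdname node_degrees
#' @export
node_strengths <- function(net) {
  stopifnot(inherits(net, "wnet"))
  s <- numeric(n_nodes(net))
  add <- rowsum(c(net$edges$weight, net$edges$weight),
                group = c(net$edges$from, net$edges$to))
  s[as.integer(rownames(add))] <- add[, 1L]
  s
}

# igraph view of a wnet; weights carried as E(g)$weight.
as_igraph <- function(net, weighted = TRUE) {
  g <- igraph::make_empty_graph(n = n_nodes(net), directed = FALSE)
  g <- igraph::add_edges(g, rbind(net$edges$from, net$edges$to))
  if (weighted) igraph::E(g)$weight <- net$edges$weight
  igraph::V(g)$name <- net$nodes$id
  g
}

# Replace the edge table, keeping nodes and canonical invariants.
replace_edges <- function(net, edges) {
  out <- net
  o <- order(edges$from, edges$to)
  out$edges <- edges[o, c("from", "to", "weight"), drop = FALSE]
  rownames(out$edges) <- NULL
  out
}

#' @export
print.wnet <- function(x, ...) {
  cat(sprintf("Weighted network: %d nodes, %d edges\n", n_nodes(x), n_edges(x)))
  if (n_edges(x) > 0) {
    cat(sprintf("  mean degree %.3f, mean weight %.4g, mean strength %.4g\n",
                mean(node_degrees(x)), mean(x$edges$weight), mean(node_strengths(x))))
  }
  cols <- intersect(c("theta", "kappa", "sigma", "x", "hemisphere"), names(x$nodes))
  if (length(cols)) cat("  node metadata:", paste(cols, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.wnet <- function(object, ...) {
  k <- node_degrees(object)
  s <- node_strengths(object)
  out <- list(n_nodes = n_nodes(object), n_edges = n_edges(object),
              mean_degree = mean(k), mean_weight = mean(object$edges$weight),
              mean_strength = mean(s),
              degree_range = range(k), weight_range = range(object$edges$weight))
  class(out) <- "summary.wnet"
  out
}

#' @export
print.summary.wnet <- function(x, ...) {
  cat(sprintf("Weighted network: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  cat(sprintf("  <k> = %.3f (range %d-%d)\n", x$mean_degree,
              x$degree_range[1], x$degree_range[2]))
  cat(sprintf("  <w> = %.4g (range %.4g-%.4g), <s> = %.4g\n", x$mean_weight,
              x$weight_range[1], x$weight_range[2], x$mean_strength))
  invisible(x)
}
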