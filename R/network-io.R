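# Readers/writers for the package's plain-text interchange formats, plus the
# fiber-density weight utility. Numbers are serialized with 17 significant
# digits, enough to reproduce every IEEE double bit-exactly on re-read.

fmt_num <- function(x) sprintf("%.17g", x)

#' Fiber-density weight
#'
#' Streamline-count weight between two regions of interest, normalized by
#' fiber length and shared surface: `w = 2 / (A_i + A_j) * sum_f 1 / l(f)`.
#'
#' @param area_i,area_j ROI surface areas in mm^2 (> 0).
#' @param fiber_lengths Lengths in mm of the fibers connecting the two ROIs
#'   (non-empty, all > 0).
#' @return The weight (a positive number).
#' @examples
#' fiber_density_weight(3, 1, c(1, 2, 4))  # 0.875
#' @export
fiber_density_weight <- function(area_i, area_j, fiber_lengths) {
  if (!length(fiber_lengths)) stop("no fibers: the regions are not connected")
  if (area_i <= 0 || area_j <= 0) stop("ROI areas must be positive")
  if (any(fiber_lengths <= 0)) stop("fiber lengths must be positive")
  2 / (area_i + area_j) * sum(1 / fiber_lengths)
}

#' Read and write weighted edge lists
#'
#' Tab-separated files with a header `from  to  weight`; endpoints are node
#' id strings and weights strictly positive. Reading rejects malformed lines,
#' non-positive weights, self-loops and duplicate undirected edges, naming the
#' offending line.
#'
#' @param path File path.
#' @param network A `wnet` object.
#' @param nodes Optional node table to attach (see [weighted_network()]).
#' @return `read_network()` returns a `wnet`; `write_network()` returns
#'   `path` invisibly.
#' @export
read_network <- function(path, nodes = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                    quote = "", comment.char = "")
  if (!all(c("from", "to", "weight") %in% names(tab)))
    stop("edge list must have columns from, to, weight")
  w <- suppressWarnings(as.numeric(tab$weight))
  bad <- which(!is.finite(w) | w <= 0)
  if (length(bad))
    stop("non-positive or malformed weight at line ", bad[1] + 1L, " of ", path)
  loops <- which(tab$from == tab$to)
  if (length(loops)) stop("self-loop at line ", loops[1] + 1L, " of ", path)
  key <- paste(pmin(tab$from, tab$to), pmax(tab$from, tab$to), sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) stop("duplicate undirected edge at line ", dup[1] + 1L, " of ", path)
  weighted_network(data.frame(from = tab$from, to = tab$to, weight = w,
                              stringsAsFactors = FALSE),
                   nodes = nodes)
}

#' @rdname read_network
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "wnet"))
  tab <- data.frame(from = network$nodes$id[network$edges$from],
                    to = network$nodes$id[network$edges$to],
                    weight = fmt_num(network$edges$weight),
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write node coordinate tables
#'
#' Tab-separated tables with columns `id`, `theta`, `kappa`, `sigma`, `x`,
#' `y`, `z`, `hemisphere` (missing values allowed in the optional columns).
#' Angular positions are normalized to `[0, 2 pi)` on read.
#'
#' @param path File path.
#' @param nodes Node data frame (as in [weighted_network()]).
#' @param network Optional `wnet`; reading errors if any of its nodes lacks a
#'   coordinate row with a finite `theta`.
#' @return `read_coordinates()` returns the node data frame.
#' @export
read_coordinates <- function(path, network = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
  if (!all(c("id", "theta") %in% names(tab)))
    stop("coordinate table must have columns id and theta")
  tab$id <- as.character(tab$id)
  tab$theta <- as.numeric(tab$theta) %% (2 * pi)
  if (!is.null(network)) {
    miss <- setdiff(network$nodes$id, tab$id[is.finite(tab$theta)])
    if (length(miss))
      stop("missing theta for network node(s): ", paste(head(miss, 5), collapse = ", "))
  }
  tab
}

#' @rdname read_coordinates
#' @export
write_coordinates <- function(nodes, path) {
  stopifnot(is.data.frame(nodes), "id" %in% names(nodes))
  out <- data.frame(id = nodes$id, stringsAsFactors = FALSE)
  for (col in c("theta", "kappa", "sigma", "x", "y", "z")) {
    if (col %in% names(nodes)) out[[col]] <- fmt_num(nodes[[col]])
  }
  if ("hemisphere" %in% names(nodes)) out$hemisphere <- nodes$hemisphere
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write layer stacks
#'
#' A layer stack is serialized as a directory with one edge list and one
#' coordinate table per layer and a JSON manifest recording the resolution
#' `r` and the node-to-supernode maps between consecutive layers.
#'
#' @param stack A `layer_stack` from [renormalize_flow()].
#' @param dir Directory path (created if needed).
#' @return `read_layer_stack()` returns a `layer_stack`.
#' @export
write_layer_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "layer_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in seq_along(stack$layers)) {
    net <- stack$layers[[l]]
    write_network(net, file.path(dir, sprintf("layer%d_edges.tsv", l - 1L)))
    write_coordinates(net$nodes, file.path(dir, sprintf("layer%d_nodes.tsv", l - 1L)))
  }
  manifest <- list(r = stack$r, n_layers = length(stack$layers),
                   maps = lapply(stack$maps, as.integer))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_layer_stack
#' @export
read_layer_stack <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  layers <- vector("list", manifest$n_layers)
  for (l in seq_len(manifest$n_layers)) {
    nodes <- read_coordinates(file.path(dir, sprintf("layer%d_nodes.tsv", l - 1L)))
    layers[[l]] <- read_network(file.path(dir, sprintf("layer%d_edges.tsv", l - 1L)),
                                nodes = nodes)
  }
  maps <- manifest$maps
  if (is.matrix(maps)) maps <- lapply(seq_len(ncol(maps)), function(i) maps[, i])
  structure(list(layers = layers, maps = lapply(maps, as.integer),
                 r = as.numeric(manifest$r)),
            class = "layer_stack")
}
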