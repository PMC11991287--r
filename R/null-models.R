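# Surrogate constructions contrasting geometry, topology and weights:
# coordinate-preserving weight reshuffling (CP-WR) and coordinate-reshuffled
# renormalization (CR-GRW), plus ensemble averaging of curves.

#' Coordinate-preserving weight reshuffling (CP-WR)
#'
#' Preserves geometry and topology but reassigns the observed weights at
#' random over the existing edges: the edge set and the weight multiset are
#' exactly those of the input, decoupling weights from topology and from the
#' underlying geometry. `cp_wr_stack()` applies the reshuffle to each layer
#' of a stack independently.
#'
#' @param network A `wnet`.
#' @param stack A `layer_stack`.
#' @param seed Integer seed.
#' @return A surrogate `wnet` (or `layer_stack`).
#' @export
cp_wr <- function(network, seed = 1L) {
  e <- network$edges
  e$weight <- with_seed(seed, sample(e$weight))
  replace_edges(network, e)
}

#' @rdname cp_wr
#' @export
cp_wr_stack <- function(stack, seed = 1L) {
  stopifnot(inherits(stack, "layer_stack"))
  seeds <- derive_seeds(seed, length(stack$layers))
  out <- stack
  out$layers <- lapply(seq_along(stack$layers), function(l)
    cp_wr(stack$layers[[l]], seed = seeds[l]))
  out
}

#' Coordinate-reshuffling renormalization (CR-GRW)
#'
#' Permutes the angular positions of the nodes uniformly at random (layer 0
#' keeps its topology and weights untouched) and then applies the sup-GRW
#' flow. Randomizing positions decouples topology and weights from the
#' geometry, so the coarse-graining no longer respects the original module
#' structure and the cross-layer self-similarity is destroyed.
#'
#' @param network A `wnet` with angular coordinates.
#' @param r,n_steps,beta As in [renormalize_flow()].
#' @param seed Integer seed for the position permutation.
#' @return A `layer_stack` whose layer 0 equals the input network.
#' @export
cr_grw <- function(network, r = 2, n_steps, seed = 1L, beta = NULL) {
  shuffled <- network
  shuffled$nodes$theta <- with_seed(seed, sample(shuffled$nodes$theta))
  renormalize_flow(shuffled, r = r, n_steps = n_steps, beta = beta)
}

#' Pointwise ensemble average of curves
#'
#' Averages realizations of a stochastic procedure that returns curves on a
#' common grid, reporting the pointwise mean and standard deviation.
#'
#' @param curves List of numeric vectors (or data frames with columns `x`
#'   and `y`) sharing one grid.
#' @return List with `mean` and `sd` (and `x` when the input carried grids).
#' @export
ensemble_average <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  if (is.data.frame(curves[[1]])) {
    x0 <- curves[[1]]$x
    for (cv in curves) {
      if (!isTRUE(all.equal(cv$x, x0))) stop("curves are on inconsistent grids")
    }
    ys <- do.call(rbind, lapply(curves, function(cv) cv$y))
    return(list(x = x0, mean = colMeans(ys),
                sd = apply(ys, 2, function(v) if (length(curves) > 1) sd(v) else 0)))
  }
  len <- unique(vapply(curves, length, integer(1)))
  if (length(len) != 1L) stop("curves are on inconsistent grids")
  ys <- do.call(rbind, curves)
  list(mean = colMeans(ys),
       sd = apply(ys, 2, function(v) if (length(curves) > 1) sd(v) else 0))
}
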