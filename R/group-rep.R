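# Distance-dependent consensus-based weighted group representative: edges are
# binned by cohort-average length, a per-bin consensus count of edges is
# retained (independently for intra- and inter-hemispheric links), and weights
# are drawn from the subject-level weight multisets (never averaged).

# Union edge table of a cohort: canonical endpoints, occurrence count, mean
# weight, the per-subject weights, cohort-average length and hemisphere class.
cohort_edge_table <- function(cohort) {
  stopifnot(inherits(cohort, "ws1_cohort") || (is.list(cohort) &&
            all(c("nodes", "subjects") %in% names(cohort))))
  nd <- cohort$nodes
  keys <- character(0)
  weights <- list()
  counts <- integer(0)
  for (net in cohort$subjects) {
    e <- net$edges
    k <- paste(e$from, e$to)
    new <- !(k %in% keys)
    if (any(new)) {
      keys <- c(keys, k[new])
      counts <- c(counts, integer(sum(new)))
      weights <- c(weights, vector("list", sum(new)))
    }
    idx <- match(k, keys)
    counts[idx] <- counts[idx] + 1L
    for (q in seq_along(idx)) {
      weights[[idx[q]]] <- c(weights[[idx[q]]], e$weight[q])
    }
  }
  ft <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  from <- as.integer(ft[, 1]); to <- as.integer(ft[, 2])
  len <- sqrt((nd$x[from] - nd$x[to])^2 + (nd$y[from] - nd$y[to])^2 +
              (nd$z[from] - nd$z[to])^2)
  data.frame(from = from, to = to, count = counts,
             mean_weight = vapply(weights, mean, numeric(1)),
             length = len,
             hemi_class = ifelse(nd$hemisphere[from] == nd$hemisphere[to],
                                 "intra", "inter"),
             weights = I(weights), stringsAsFactors = FALSE)
}

#' Distance bins for consensus selection
#'
#' Bins every edge observed in at least one subject by its cohort-average
#' length (the Euclidean distance between the shared node positions) into
#' `n_bins` bins, either equal-width over the observed length range (the
#' default) or equal-occupancy quantile bins.
#'
#' @param cohort A cohort (e.g. from [generate_cohort()]): shared `nodes`
#'   with positions and hemisphere labels, plus a list of `subjects`.
#' @param n_bins Number of bins (default 22).
#' @param method `"width"` (equal-width) or `"quantile"`.
#' @return List of class `distance_bins`: the union `edges` table with a
#'   `bin` column, plus `breaks`, `n_bins`, `method`.
#' @export
build_distance_bins <- function(cohort, n_bins = 22, method = c("width", "quantile")) {
  method <- match.arg(method)
  et <- cohort_edge_table(cohort)
  if (any(!is.finite(et$length)))
    stop("missing length proxy for edges: ",
         paste(head(paste(et$from, et$to, sep = "-")[!is.finite(et$length)], 5),
               collapse = ", "))
  if (method == "width") {
    breaks <- seq(min(et$length), max(et$length), length.out = n_bins + 1L)
  } else {
    breaks <- unique(quantile(et$length, probs = seq(0, 1, length.out = n_bins + 1L)))
  }
  if (length(breaks) < 2L) breaks <- c(breaks[1] * 0.999, breaks[1] * 1.001)
  et$bin <- findInterval(et$length, breaks, rightmost.closed = TRUE,
                         all.inside = TRUE)
  structure(list(edges = et, breaks = breaks, n_bins = n_bins, method = method),
            class = "distance_bins")
}

#' Consensus edge selection
#'
#' Within each distance bin and hemisphere class (intra/inter), keeps the
#' `round(n_bar)` most frequently occurring edges, where `n_bar` is the mean
#' over subjects of the number of that subject's edges falling in the bin and
#' class; rounding is half-up. Ties on occurrence are broken by higher
#' average weight, then by canonical edge index.
#'
#' @param cohort A cohort.
#' @param bins A [build_distance_bins()] result.
#' @return The union edge table restricted to the selected edges, with a
#'   `retained` attribute data frame recording per-(bin, class) targets.
#' @export
consensus_select <- function(cohort, bins) {
  stopifnot(inherits(bins, "distance_bins"))
  et <- bins$edges
  n_subj <- length(cohort$subjects)
  sel <- logical(nrow(et))
  prov <- NULL
  for (cls in unique(et$hemi_class)) {
    for (b in sort(unique(et$bin[et$hemi_class == cls]))) {
      cand <- which(et$bin == b & et$hemi_class == cls)
      # mean per-subject count: each subject contributes its own edges in
      # this (bin, class); an edge present in c subjects contributes c.
      n_bar <- sum(et$count[cand]) / n_subj
      keep_n <- floor(n_bar + 0.5)
      if (keep_n > length(cand)) keep_n <- length(cand)
      if (keep_n > 0L) {
        o <- cand[order(-et$count[cand], -et$mean_weight[cand], cand)]
        sel[o[seq_len(keep_n)]] <- TRUE
      }
      prov <- rbind(prov, data.frame(bin = b, hemi_class = cls,
                                     candidates = length(cand),
                                     mean_subject_count = n_bar,
                                     retained = min(keep_n, length(cand))))
    }
  }
  out <- et[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retained") <- prov
  out
}

#' Subject-sampled group weights
#'
#' Assigns to each selected edge a weight drawn uniformly at random from the
#' multiset of subject-level weights observed for that edge (no averaging,
#' which would distort the weighted properties).
#'
#' @param selected Edge table from [consensus_select()].
#' @param cohort The cohort the selection came from.
#' @param seed Integer seed.
#' @return A `wnet` over the cohort's shared node table.
#' @export
assign_group_weights <- function(selected, cohort, seed = 1L) {
  w <- with_seed(seed, vapply(selected$weights, function(ws)
    ws[[sample.int(length(ws), 1L)]], numeric(1)))
  weighted_network(data.frame(from = selected$from, to = selected$to,
                              weight = w),
                   nodes = cohort$nodes)
}

#' Distance-dependent weighted group representative
#'
#' End-to-end construction: distance bins by cohort-average edge length,
#' per-bin consensus selection split by hemisphere class, and
#' subject-sampled weights.
#'
#' @inheritParams build_distance_bins
#' @param seed Integer seed for the weight sampling.
#' @return A `wnet`; provenance (bin breaks and per-bin retention) is stored
#'   in `attr(net, "provenance")`.
#' @export
group_representative <- function(cohort, n_bins = 22,
                                 method = c("width", "quantile"), seed = 1L) {
  bins <- build_distance_bins(cohort, n_bins = n_bins, method = method)
  selected <- consensus_select(cohort, bins)
  net <- assign_group_weights(selected, cohort, seed = seed)
  attr(net, "provenance") <- list(seed = seed, breaks = bins$breaks,
                                  method = bins$method,
                                  retained = attr(selected, "retained"))
  net
}
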