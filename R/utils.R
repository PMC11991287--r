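# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so seeded helpers do not perturb each other.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  code
}

# Derive a stream of independent sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# Shorter-arc angular separation, vectorized; result in [0, pi].
delta_theta <- function(theta_i, theta_j) {
  d <- abs(theta_i - theta_j) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# All unordered pairs of 1..n as parallel index vectors with i < j.
pair_indices <- function(n) {
  n <- as.integer(n)
  if (n < 2L) return(list(i = integer(0), j = integer(0)))
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  list(i = i, j = j)
}

# Two-sample Kolmogorov-Smirnov distance, tie-safe.
#' Two-sample Kolmogorov-Smirnov distance
#'
#' Supremum of the absolute difference between the empirical cumulative
#' distribution functions of two samples. Used throughout to quantify the
#' overlap of rescaled weight/strength/degree distributions across
#' renormalization layers.
#'
#' @param x,y Numeric vectors.
#' @return A single number in \[0, 1\].
#' @export
ks_distance <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  z <- sort(unique(c(x, y)))
  max(abs(ecdf(x)(z) - ecdf(y)(z)))
}

# Geometric (log-spaced) bin edges over the range of positive x.
log_bin_edges <- function(x, n_bins) {
  stopifnot(all(x > 0), n_bins >= 1)
  r <- range(x)
  if (r[1] == r[2]) r <- r * c(0.999, 1.001)
  exp(seq(log(r[1]), log(r[2]), length.out = n_bins + 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
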