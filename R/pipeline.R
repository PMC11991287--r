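# Orchestration: end-to-end analyses over a synthetic WS1 specification or
# files on disk, emitting per-layer observable tables and JSON summaries.
# A single seed in the config fixes every stochastic stage.

# Resolve a config given as a list or as a path to a JSON or YAML file.
resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config) &&
                  requireNamespace("yaml", quietly = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  config
}

# Build the layer-0 network named by the config: either a synthetic WS1 spec
# (fields under $model) or a pair of files ($network_file, $coordinates_file).
config_network <- function(config) {
  if (!is.null(config$network_file)) {
    nodes <- if (!is.null(config$coordinates_file))
      read_coordinates(config$coordinates_file) else NULL
    return(read_network(config$network_file, nodes = nodes))
  }
  m <- config$model %||% list()
  params <- ws1_params(
    n_nodes = m$n_nodes %||% 2000L, beta = m$beta %||% 2.5,
    tau = m$tau %||% 0.5, a = m$a %||% 1, eta = m$eta %||% 0.9,
    mean_degree = m$mean_degree %||% 15,
    seed = config$seed %||% 1L)
  sample_ws1(params)
}

config_stack <- function(config, net = NULL) {
  if (is.null(net)) net <- config_network(config)
  renormalize_flow(net, r = config$r %||% 2, n_steps = config$n_steps %||% 4,
                   beta = attr(net, "params")$beta)
}

layer_observables <- function(net) {
  rs <- layer_rescale(net)
  list(weight_ccdf = ccdf(rs$weight),
       strength_ccdf = ccdf(rs$strength[rs$strength > 0]),
       degree_ccdf = ccdf(rs$degree[rs$degree > 0]),
       sk_profile = strength_degree_profile(net),
       disparity = disparity_profile(net))
}

cross_layer_ks <- function(stack, what = c("weight", "strength", "degree")) {
  what <- match.arg(what)
  vals <- lapply(stack$layers, function(net) {
    rs <- layer_rescale(net)
    v <- rs[[what]]
    v[v > 0]
  })
  L <- length(vals)
  ks <- matrix(0, L, L, dimnames = list(paste0("l", 0:(L - 1)),
                                        paste0("l", 0:(L - 1))))
  for (a in seq_len(L - 1)) {
    for (b in (a + 1):L) {
      ks[a, b] <- ks[b, a] <- ks_distance(vals[[a]], vals[[b]])
    }
  }
  ks
}

write_report_outputs <- function(report, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report$summary, file.path(out_dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(NULL)
}

#' Self-similarity report
#'
#' Generates (or loads) a layer-0 network, unfolds it with the sup-GRW flow,
#' and reports per-layer observables (rescaled weight/strength/degree CCDFs,
#' strength-degree relation with its exponent, disparity with its null band)
#' plus cross-layer Kolmogorov-Smirnov tables.
#'
#' @param config List (or JSON file path) with optional fields `model`
#'   (`n_nodes`, `beta`, `tau`, `eta`, `a`, `mean_degree`), `network_file` /
#'   `coordinates_file`, `r`, `n_steps`, `seed`, `out_dir`.
#' @return List of class `grw_report` with `layers` (observables per layer),
#'   `ks` (matrices for weight, strength, degree) and `summary`.
#' @export
run_self_similarity <- function(config = list()) {
  config <- resolve_config(config)
  stack <- config_stack(config)
  obs <- lapply(stack$layers, layer_observables)
  ks <- list(weight = cross_layer_ks(stack, "weight"),
             strength = cross_layer_ks(stack, "strength"),
             degree = cross_layer_ks(stack, "degree"))
  consec <- function(m) mean(m[cbind(seq_len(nrow(m) - 1), seq_len(nrow(m) - 1) + 1)])
  summary <- list(
    n_layers = length(stack$layers),
    layer_sizes = vapply(stack$layers, n_nodes, integer(1)),
    mean_degree = vapply(stack$layers, function(x) mean(node_degrees(x)), numeric(1)),
    mean_weight = vapply(stack$layers, function(x) mean(x$edges$weight), numeric(1)),
    eta_by_layer = vapply(obs, function(o) o$sk_profile$eta, numeric(1)),
    ks_consecutive = vapply(ks, consec, numeric(1)))
  report <- structure(list(layers = obs, ks = ks, stack = stack,
                           summary = summary), class = "grw_report")
  write_report_outputs(report, config$out_dir, "self_similarity")
  report
}

#' Weak-ties report
#'
#' Louvain partitions per layer (computed independently on each layer,
#' unweighted mode) and both weak-ties spectra, plus the intra/inter-modular
#' mean-weight comparison.
#'
#' @inheritParams run_self_similarity
#' @return A `grw_report` with per-layer `partition`, `spectrum_weight`,
#'   `spectrum_confidence`, `intra_inter`.
#' @export
run_weak_ties <- function(config = list()) {
  config <- resolve_config(config)
  seed <- config$seed %||% 1L
  stack <- config_stack(config)
  percents <- config$percents %||% c(1, 2, 5, 10, 20, 50, 100)
  seeds <- derive_seeds(seed, length(stack$layers))
  per_layer <- lapply(seq_along(stack$layers), function(l) {
    net <- stack$layers[[l]]
    part <- detect_modules(net, seed = seeds[l])
    list(partition = part,
         spectrum_weight = weak_ties_spectrum(net, part, "weight", percents),
         spectrum_confidence = weak_ties_spectrum(net, part, "confidence", percents),
         intra_inter = tryCatch(intra_inter_mean_weights(net, part),
                                error = function(e) c(intra = NA, inter = NA)))
  })
  summary <- list(
    n_modules = vapply(per_layer, function(x) length(unique(x$partition)), numeric(1)),
    rho_at_min_percent = vapply(per_layer, function(x)
      x$spectrum_weight$rho[1], numeric(1)),
    intra = vapply(per_layer, function(x) unname(x$intra_inter["intra"]), numeric(1)),
    inter = vapply(per_layer, function(x) unname(x$intra_inter["inter"]), numeric(1)))
  report <- structure(list(layers = per_layer, stack = stack, summary = summary),
                      class = "grw_report")
  write_report_outputs(report, config$out_dir, "weak_ties")
  report
}

#' Null-model report
#'
#' CP-WR surrogates per layer and CR-GRW reshuffled flows, averaged over
#' `reps` realizations: cross-layer KS distances and the flatness of the
#' weak-ties spectrum on surrogates versus the original.
#'
#' @inheritParams run_self_similarity
#' @return A `grw_report` with `cpwr` and `crgrw` ensemble summaries.
#' @export
run_nulls <- function(config = list()) {
  config <- resolve_config(config)
  seed <- config$seed %||% 1L
  reps <- config$reps %||% 10L
  net <- config_network(config)
  stack <- config_stack(config, net)
  seeds <- derive_seeds(seed, 2L * reps)
  l_last <- min(3L, length(stack$layers))

  grw_ks_s <- cross_layer_ks(stack, "strength")[1, l_last]
  grw_ks_k <- cross_layer_ks(stack, "degree")[1, l_last]

  cpwr_eta <- numeric(reps)
  cpwr_flat <- numeric(reps)
  part0 <- detect_modules(stack$layers[[1]], seed = seed)
  rho_orig <- weak_ties_spectrum(stack$layers[[1]], part0, "weight")$rho
  for (q in seq_len(reps)) {
    sur <- cp_wr(stack$layers[[1]], seed = seeds[q])
    cpwr_eta[q] <- strength_degree_profile(sur)$eta
    cpwr_flat[q] <- max(abs(weak_ties_spectrum(sur, part0, "weight")$rho - 1))
  }

  crgrw_ks_s <- numeric(reps)
  crgrw_ks_k <- numeric(reps)
  for (q in seq_len(reps)) {
    cstack <- cr_grw(net, r = stack$r, n_steps = length(stack$layers) - 1L,
                     seed = seeds[reps + q], beta = attr(net, "params")$beta)
    crgrw_ks_s[q] <- cross_layer_ks(cstack, "strength")[1, l_last]
    crgrw_ks_k[q] <- cross_layer_ks(cstack, "degree")[1, l_last]
  }
  summary <- list(
    reps = reps,
    eta_original = strength_degree_profile(stack$layers[[1]])$eta,
    eta_cpwr_mean = mean(cpwr_eta), eta_cpwr_sd = sd(cpwr_eta),
    spectrum_flatness_original = max(abs(rho_orig - 1)),
    spectrum_flatness_cpwr_mean = mean(cpwr_flat),
    grw_ks_strength = grw_ks_s, crgrw_ks_strength_mean = mean(crgrw_ks_s),
    grw_ks_degree = grw_ks_k, crgrw_ks_degree_mean = mean(crgrw_ks_k))
  report <- structure(list(summary = summary), class = "grw_report")
  write_report_outputs(report, config$out_dir, "nulls")
  report
}

#' Group-representative report
#'
#' Generates a synthetic cohort (or uses a supplied one), builds the
#' distance-dependent weighted group representative and reports retention
#' provenance and weighted summaries.
#'
#' @inheritParams run_self_similarity
#' @param cohort Optional pre-built cohort; otherwise generated from
#'   `config$model` with `config$n_subjects` subjects.
#' @return A `grw_report` with the `group` network and `summary`.
#' @export
run_group <- function(config = list(), cohort = NULL) {
  config <- resolve_config(config)
  seed <- config$seed %||% 1L
  if (is.null(cohort)) {
    m <- config$model %||% list()
    params <- ws1_params(n_nodes = m$n_nodes %||% 400L, beta = m$beta %||% 2.5,
                         tau = m$tau %||% 0.5, eta = m$eta %||% 0.9,
                         mean_degree = m$mean_degree %||% 15, seed = seed)
    cohort <- generate_cohort(params, n_subjects = config$n_subjects %||% 40L,
                              subject_variability = config$subject_variability %||% 0.1,
                              seed = seed)
  }
  group <- group_representative(cohort, n_bins = config$n_bins %||% 22,
                                seed = seed)
  subj_edges <- vapply(cohort$subjects, n_edges, integer(1))
  summary <- list(
    n_subjects = length(cohort$subjects),
    mean_subject_edges = mean(subj_edges),
    group_edges = n_edges(group),
    retained = attr(group, "provenance")$retained)
  report <- structure(list(group = group, cohort = cohort, summary = summary),
                      class = "grw_report")
  write_report_outputs(report, config$out_dir, "group")
  report
}

#' @export
print.grw_report <- function(x, ...) {
  cat("grwnet analysis report\n")
  utils::str(x$summary, max.level = 1, give.attr = FALSE)
  invisible(x)
}
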