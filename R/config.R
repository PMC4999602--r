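#' Read and write analysis configuration
#'
#' A YAML configuration carries everything needed to reproduce an
#' analysis: the model family, effect type, class effects, priors, MCMC
#' settings, and (for simulation) a truth block.  [mbnma_config()] parses
#' and validates a file; the helpers turn config blocks into the package
#' objects.  [write_manifest()] records the provenance of an output
#' directory (inputs, seed, package version, config) so results are
#' regenerable from the manifest alone.
#'
#' Recognized top-level blocks:
#' * `model`: `family` (lumped/split/ume or a dose-response name),
#'   `effect`, `class_effect`, `priors` (named JAGS strings).
#' * `mcmc`: `chains`, `burnin`, `sample`, `thin`, `seed`, `preset`.
#' * `truth`: arguments of [network_truth()] (`params` as a named map of
#'   per-agent lists), plus optional `inconsistency: {edge, offset}`.
#' * `predict`: `doses` (vector or per-agent map), `mode`.
#'
#' @param path YAML file path.
#' @return the parsed configuration list, classed `mbnma_config`.
#' @export
mbnma_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "mbnma_config")
}

#' @rdname mbnma_config
#' @param cfg a parsed configuration (or its `mcmc` / `truth` / `model`
#'   block).
#' @export
as_mcmc_control <- function(cfg) {
  b <- cfg$mcmc %||% cfg
  do.call(mcmc_control, b[intersect(names(b),
    c("chains", "burnin", "sample", "thin", "seed", "preset"))])
}

#' @rdname mbnma_config
#' @export
as_network_truth <- function(cfg) {
  b <- cfg$truth %||% cfg
  b$inconsistency <- NULL
  if (!is.null(b$params)) b$params <- lapply(b$params, unlist)
  if (!is.null(b$doses)) b$doses <- unlist(b$doses)
  do.call(network_truth, b)
}

#' @rdname mbnma_config
#' @export
as_priors <- function(cfg) {
  b <- cfg$model$priors %||% cfg$priors %||% cfg
  if (!is.null(b$class_sd)) b$class_sd <- unlist(b$class_sd)
  do.call(mbnma_priors, b[intersect(names(b),
    c("effect", "mu", "between_sd", "class_mean", "class_sd"))])
}

#' @rdname mbnma_config
#' @param dir output directory.
#' @param ... named provenance entries (input paths, seed, config).
#' @export
write_manifest <- function(dir, ...) {
  manifest <- list(tool = "dosenma",
                   version = as.character(utils::packageVersion("dosenma")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   ...)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
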