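#' MCMC run settings
#'
#' Defaults follow the estimation protocol used throughout the package's
#' reference analyses: three independent chains, 40,000 burn-in
#' iterations, 40,000 sampling iterations with a thinning parameter of 10.
#' The `"test"` preset (3 chains, 2,000 + 2,000, thin 1) is a reduced
#' configuration for simulation studies and test suites.
#'
#' @param chains number of independent chains (>= 2 for convergence
#'   diagnostics).
#' @param burnin burn-in iterations per chain (includes the adaptation
#'   phase).
#' @param sample post-burn-in iterations per chain.
#' @param thin thinning interval; `sample / thin` draws are retained per
#'   chain (at least 100 required, so summaries are usable).
#' @param seed master seed; per-chain sampler seeds and overdispersed
#'   starting values are derived from it, making runs exactly
#'   reproducible.
#' @param preset `"full"` (the defaults) or `"test"`; explicit arguments
#'   override the preset.
#' @return an object of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 3, burnin = 40000, sample = 40000,
                         thin = 10, seed = 1, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("full", "test"))
    if (preset == "test") {
      if (missing(burnin)) burnin <- 2000
      if (missing(sample)) sample <- 2000
      if (missing(thin)) thin <- 1
    }
  }
  stopifnot(chains >= 1, burnin >= 0, sample > 0, thin >= 1)
  if (sample / thin < 100)
    stop("fewer than 100 retained draws per chain; increase sample or ",
         "decrease thin")
  structure(list(chains = as.integer(chains), burnin = as.integer(burnin),
                 sample = as.integer(sample), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_control")
}

#' Fit a (model-based) network meta-analysis
#'
#' The single entry point for all synthesis models: lumped and split
#' network meta-analysis, model-based NMA with a parametric dose-response
#' function, and the unrelated-mean-effects inconsistency model.  Builds
#' the joint Bayesian model with [mbnma_model()] and estimates it by Gibbs
#' sampling (JAGS), then computes posterior summaries, split-chain
#' Gelman-Rubin diagnostics, and the residual-deviance / plug-in DIC
#' report.
#'
#' @inheritParams mbnma_model
#' @param control an [mcmc_control()] object.
#' @param quiet suppress sampler progress output.
#' @return An object of class `mbnma` with components `samples` (a
#'   [coda::mcmc.list] of monitored parameters), `fitted` (per-draw fitted
#'   probabilities per arm), `summary`, `rhat`, `deviance` (a
#'   `deviance_report`), and the model bookkeeping.  Methods:
#'   `print`, `summary`, `coef`, `predict`, `plot`, `residuals`,
#'   `simulate`.
#' @examples
#' \donttest{
#' net <- simulate_network(network_truth(n_studies = 15), seed = 1)
#' fit <- mbnma(net, model = "emax", effect = "random",
#'              control = mcmc_control(preset = "test"))
#' summary(fit)
#' }
#' @export
mbnma <- function(network, model = "emax", effect = c("random", "fixed"),
                  class_effect = NULL, priors = mbnma_priors(),
                  control = mcmc_control(), quiet = TRUE) {
  effect <- match.arg(effect)
  mod <- mbnma_model(network, model = model, effect = effect,
                     class_effect = class_effect, priors = priors)
  fit_built_model(mod, control, quiet)
}

fit_built_model <- function(mod, control, quiet = TRUE) {
  stopifnot(inherits(mod, "mbnma_model"), inherits(control, "mcmc_control"))
  samp <- run_jags(mod$code, mod$data, mod$inits, mod$monitors, control,
                   quiet)
  sel <- grepl("^p\\[", coda::varnames(samp))
  fitted_draws <- as.matrix(do.call(rbind, lapply(samp, function(ch)
    as.matrix(ch[, sel, drop = FALSE]))))
  params <- samp[, !sel, drop = FALSE]

  # fitted-probability columns in arm order
  want <- sprintf("p[%d,%d]", mod$arm_map$i, mod$arm_map$k)
  fitted_draws <- fitted_draws[, want, drop = FALSE]

  dev <- plugin_dic(fitted_draws, observed = mod$arm_map$responders,
                    family = "binomial", n = mod$arm_map$sample_size,
                    labels = mod$arm_map[c("study", "agent", "dose_std",
                                           "treatment")])
  rh <- split_rhat(params)
  if (any(rh > 1.05, na.rm = TRUE))
    warning("possible non-convergence: split-Rhat > 1.05 for ",
            paste(names(rh)[which(rh > 1.05)], collapse = ", "))

  fit <- structure(
    list(model = mod$family, effect = mod$effect,
         dose_model = mod$dose_model, class_pars = mod$class_pars,
         priors = mod$priors, control = control, network = mod$network,
         treatments = mod$treatments, pairs = mod$pairs,
         arm_map = mod$arm_map, code = mod$code,
         samples = params, fitted = fitted_draws,
         deviance = dev, rhat = rh,
         data_sig = data_signature(mod$arm_map)),
    class = "mbnma")
  fit$summary <- posterior_summary(fit)
  fit
}

run_jags <- function(code, data, inits, monitors, control, quiet = TRUE) {
  # block-updating of the logistic likelihood mixes much better on the
  # ridged Emax posterior than one-at-a-time slice sampling
  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  ini <- lapply(seq_len(control$chains), function(ch)
    inits(ch, control$seed))
  n_adapt <- min(5000L, control$burnin)
  jm <- rjags::jags.model(textConnection(code), data = data, inits = ini,
                          n.chains = control$chains, n.adapt = n_adapt,
                          quiet = quiet)
  if (control$burnin > n_adapt)
    stats::update(jm, control$burnin - n_adapt,
                  progress.bar = if (quiet) "none" else "text")
  rjags::coda.samples(jm, variable.names = monitors,
                      n.iter = control$sample, thin = control$thin,
                      progress.bar = if (quiet) "none" else "text")
}

data_signature <- function(arm_map) {
  paste(arm_map$study, arm_map$agent, arm_map$dose_std, arm_map$responders,
        arm_map$sample_size, sep = ":", collapse = ";")
}

#' Random-effects model for the placebo arms
#'
#' Fits the placebo (reference-agent) arms alone: the arm log-odds are
#' exchangeable normal around a mean `m` with SD `s`.  Run separately from
#' the relative-effect models — the two share no parameters, so anchoring
#' predictions on the placebo model cannot bias the relative effects.
#' `m` is the "typical trial" placebo log-odds used by
#' [predict.mbnma()].
#'
#' @param network a [dose_network()] object with at least two
#'   reference-agent arms (one arm leaves the SD unidentified).
#' @param priors an [mbnma_priors()] object; `mu` is used for the mean `m`
#'   and `between_sd` for `s`.
#' @param control an [mcmc_control()] object.
#' @param quiet suppress sampler progress output.
#' @return an object of class `mbnma_placebo` with draws of `m` and `sdp`.
#' @export
placebo_model <- function(network, priors = mbnma_priors(),
                          control = mcmc_control(), quiet = TRUE) {
  stopifnot(inherits(network, "dose_network"))
  plac <- network$arms[network$arms$agent == network$reference, ,
                       drop = FALSE]
  if (nrow(plac) == 0)
    stop("no ", network$reference, " arms in the network")
  if (nrow(plac) == 1)
    stop("a single ", network$reference,
         " arm cannot identify the between-trial SD")
  code <- paste0(
    "model {\n",
    "  for (j in 1:np) {\n",
    "    rp[j] ~ dbin(pp[j], nn[j])\n",
    "    logit(pp[j]) <- mup[j]\n",
    "    mup[j] ~ dnorm(m, taup)\n",
    "  }\n",
    "  m ~ ", priors$mu, "\n",
    "  sdp ~ ", priors$between_sd, "\n",
    "  taup <- pow(sdp, -2)\n",
    "}\n")
  data <- list(np = nrow(plac), rp = plac$responders,
               nn = plac$sample_size)
  inits <- function(chain, seed) {
    set.seed((seed %% 100000L) * 37L + chain)
    list(m = stats::rnorm(1, 0, 1), sdp = stats::runif(1, 0.1, 1),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed %% 100000L) * 100L + 50L + chain)
  }
  samp <- run_jags(code, data, inits, c("m", "sdp"), control, quiet)
  structure(list(samples = samp, arms = plac, control = control,
                 rhat = split_rhat(samp),
                 reference = network$reference),
            class = "mbnma_placebo")
}

#' @export
print.mbnma_placebo <- function(x, ...) {
  s <- posterior_summary(x$samples)
  cat("Placebo random-effects model (", nrow(x$arms), " arms)\n", sep = "")
  print(s, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
print.mbnma <- function(x, ...) {
  cat("Model-based network meta-analysis fit\n")
  cat("  family: ", x$model,
      if (!is.null(x$dose_model)) paste0(" (", x$dose_model$name, ")"),
      ", ", x$effect, " effects\n", sep = "")
  if (length(x$class_pars))
    cat("  exchangeable across agents: ",
        paste(x$class_pars, collapse = ", "), "\n", sep = "")
  cat("  studies: ", length(x$network$studies), ", data points: ",
      nrow(x$arm_map), "\n", sep = "")
  cat("  DIC: ", format(x$deviance$DIC, digits = 5), "  (pD = ",
      format(x$deviance$pD, digits = 4), ", mean residual deviance = ",
      format(x$deviance$Dbar, digits = 5), ")\n", sep = "")
  cat("  max split-Rhat: ", format(max(x$rhat, na.rm = TRUE), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.mbnma <- function(object, ...) {
  structure(list(fit = object, table = object$summary),
            class = "summary.mbnma")
}

#' @export
print.summary.mbnma <- function(x, ...) {
  print(x$fit)
  cat("\nPosterior summaries (median and 95% credible interval):\n")
  tab <- x$table
  tab <- tab[!grepl("^mu\\[", tab$parameter), , drop = FALSE]
  print(tab, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.mbnma <- function(object, ...) {
  tab <- object$summary
  tab <- tab[!grepl("^mu\\[", tab$parameter), , drop = FALSE]
  stats::setNames(tab$median, tab$label)
}

#' Deviance residuals of a synthesis model
#'
#' Signed square roots of the per-arm posterior-mean residual-deviance
#' contributions; under a well-fitting model each squared residual is
#' expected to contribute about 1.
#'
#' @param object an [mbnma()] fit.
#' @param ... unused.
#' @return numeric vector, one element per arm (data point).
#' @export
residuals.mbnma <- function(object, ...) {
  pp <- object$deviance$per_point
  obs <- pp$responders / pp$sample_size
  fit <- colMeans(object$fitted)
  sign(obs - fit) * sqrt(pp$contribution)
}
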