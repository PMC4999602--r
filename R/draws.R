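# Reconstruction of arm-level quantities from monitored parameter draws.
# Keeping the monitor list small (parameters + fitted probabilities) and
# rebuilding relative-effect means in R exercises the same dose-response
# code used for prediction.

# Named list, per active agent, of per-parameter posterior draw vectors.
dr_param_draws <- function(fit) {
  stopifnot(!is.null(fit$dose_model))
  draws <- pooled_draws(fit$samples)
  agents <- fit$network$agents
  out <- list()
  for (a in seq_along(agents)[-1]) {
    theta <- lapply(fit$dose_model$pars, function(p)
      draws[, sprintf("%s[%d]", p, a)])
    names(theta) <- fit$dose_model$pars
    out[[agents[a]]] <- theta
  }
  out
}

# Draws of f(x, agent) on the log-odds scale; 0 for the reference agent.
f_draws <- function(fit, agent, dose, params = NULL) {
  if (agent == fit$network$reference)
    return(rep(0, nrow(pooled_draws(fit$samples))))
  params <- params %||% dr_param_draws(fit)
  if (!agent %in% names(params)) stop("unknown agent: ", agent)
  fit$dose_model$fun(dose, params[[agent]])
}

# Matrix (draws x data points) of the model-mean relative effect of every
# arm versus its study's arm 1 (zero for arm 1 itself).
arm_md_draws <- function(fit) {
  draws <- pooled_draws(fit$samples)
  am <- fit$arm_map
  out <- matrix(0, nrow(draws), nrow(am))
  if (fit$model %in% c("lumped", "split")) {
    tcol <- function(tr) draws[, sprintf("d[%d]",
      match(tr, fit$treatments$treatment))]
    for (j in which(am$k > 1)) {
      t1 <- am$treatment[am$i == am$i[j] & am$k == 1]
      out[, j] <- tcol(am$treatment[j]) - tcol(t1)
    }
  } else if (fit$model == "ume") {
    for (j in which(am$k > 1)) {
      t1 <- am$treatment[am$i == am$i[j] & am$k == 1]
      pr <- which(fit$pairs$treatment1 == t1 &
                    fit$pairs$treatment2 == am$treatment[j])
      out[, j] <- draws[, sprintf("dd[%d]", pr)]
    }
  } else {
    params <- dr_param_draws(fit)
    fvals <- matrix(0, nrow(draws), nrow(am))
    for (j in seq_len(nrow(am)))
      fvals[, j] <- f_draws(fit, am$agent[j], am$dose_std[j], params)
    for (j in which(am$k > 1)) {
      j1 <- which(am$i == am$i[j] & am$k == 1)
      out[, j] <- fvals[, j] - fvals[, j1]
    }
  }
  out
}

mu_draws <- function(fit) {
  draws <- pooled_draws(fit$samples)
  ns <- length(fit$network$studies)
  draws[, sprintf("mu[%d]", seq_len(ns)), drop = FALSE]
}

sd_draws <- function(fit) {
  if (fit$effect != "random") return(NULL)
  pooled_draws(fit$samples)[, "sd"]
}
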