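#' Build a joint Bayesian model without fitting it
#'
#' Assembles the JAGS model code, data block, monitors and initial-value
#' generator for a synthesis model on a dose network.  [mbnma()] calls
#' this internally; it is exported so the generated code can be inspected
#' and so alternative Gibbs engines could run the same model.
#'
#' All families share the binomial-logit likelihood: arm k of study i has
#' `r[i,k] ~ Binomial(n[i,k], p[i,k])` with
#' `logit(p[i,k]) = mu[i] + delta[i,k]`, where `mu[i]` is the study's
#' arm-1 log-odds, treated as an independent nuisance parameter so that
#' concurrent control is respected, and `delta[i,1] = 0`.  The families
#' differ in the mean model for `delta[i,k]`:
#'
#' * `"lumped"` / `"split"`: network meta-analysis with one basic
#'   parameter per non-reference node (agent, or agent-dose combination);
#'   all other contrasts follow by consistency.
#' * a dose-response model name or [dose_response()] object: model-based
#'   NMA, where the mean of `delta[i,k]` is
#'   `f(x[i,k], t[i,k]) - f(x[i,1], t[i,1])`.
#' * `"ume"`: unrelated mean effects — one free mean per treatment pair
#'   directly compared within some study (split coding, no consistency,
#'   no dose-response); used to probe inconsistency.
#'
#' Under `effect = "random"` the study effects are exchangeable normal
#' around the mean model with a single between-study SD common to all
#' contrasts; multi-arm trials use the sequential-conditional scheme of
#' [rmultiarm_delta()] so their correlated effects (covariance
#' sigma^2 / 2) are handled exactly.
#'
#' @param network a [dose_network()] object.
#' @param model `"lumped"`, `"split"`, `"ume"`, a dose-response model name
#'   (`"emax"`, `"linear"`, `"linear_intercept"`, or a registered custom
#'   name), or a [dose_response()] object.
#' @param effect `"random"` or `"fixed"`.
#' @param class_effect for dose-response families only: character vector
#'   of parameters to make exchangeable across agents (for the Emax model,
#'   any of `"emax"`, `"ed50"`), each drawn from a common normal with a
#'   vague-mean and uniform-SD hyperprior; borrows strength across agents.
#' @param priors an [mbnma_priors()] object.
#' @return an object of class `mbnma_model` with elements `code`, `data`,
#'   `monitors`, `inits` (function of chain and seed), and bookkeeping
#'   (`arm_map`, `treatments`, `pairs`, `family`, `effect`, ...).
#' @export
mbnma_model <- function(network, model = "emax",
                        effect = c("random", "fixed"),
                        class_effect = NULL, priors = mbnma_priors()) {
  stopifnot(inherits(network, "dose_network"),
            inherits(priors, "mbnma_priors"))
  effect <- match.arg(effect)

  is_name <- is.character(model) && length(model) == 1
  family <- if (inherits(model, "dose_response")) "mbnma"
            else if (is_name && model %in% c("lumped", "split", "ume")) model
            else "mbnma"
  dr <- if (family == "mbnma") get_dose_response(model) else NULL

  if (!is.null(class_effect) && length(class_effect) && family != "mbnma")
    stop("class effects are only defined for dose-response models")

  level <- if (family == "lumped") "agent" else "treatment"
  network$coding <- if (level == "agent") "lumped" else "split"
  dat <- jags_network_data(network, level)

  if (family %in% c("lumped", "split", "mbnma")) {
    chk_level <- if (family == "mbnma") "agent" else level
    es <- network_summary(network, level = chk_level)
    if (!attr(es, "connected")) {
      comps <- attr(es, "components")
      stop("coded network is disconnected; components: ",
           paste(vapply(comps, function(x) paste(x, collapse = ","), ""),
                 collapse = " | "))
    }
  }

  class_pars <- character(0)
  if (family == "mbnma") {
    class_pars <- resolve_class_pars(dr, class_effect)
    if (length(class_pars) && length(network$agents) < 3)
      stop("class effects need at least 2 active agents")
  }

  pairs <- NULL
  if (family == "ume") {
    pairs <- ume_pairs(dat)
    dat$data$pr <- pairs$pr
    dat$data$npair <- nrow(pairs$table)
  }

  code <- build_jags_code(family, effect, dr, priors, class_pars)

  monitors <- c("mu", "p",
                switch(family,
                       lumped = "d", split = "d", ume = "dd",
                       mbnma = dr$pars),
                if (family == "mbnma" && length(class_pars))
                  c(paste0("m_", class_pars), paste0("sd_", class_pars)),
                if (effect == "random") "sd")

  keep <- c("ns", "na", "r", "n",
            switch(family, mbnma = c("agent", "x", "nagent"),
                   ume = c("pr", "npair"), c("t", "nt")))
  data <- dat$data[keep]

  info <- list(family = family, effect = effect, dr = dr,
               class_pars = class_pars, priors = priors)
  inits <- make_inits(info, dat)

  structure(list(code = code, data = data, monitors = monitors,
                 inits = inits, family = family, effect = effect,
                 dose_model = dr, class_pars = class_pars,
                 priors = priors, network = network,
                 treatments = dat$treatments, arm_map = dat$arm_map,
                 pairs = if (is.null(pairs)) NULL else pairs$table),
            class = "mbnma_model")
}

# Map user-facing class-effect names (e.g. "ed50") to sampled parameters
# (e.g. "led50") via the model's summary transforms, and check they admit
# a class effect.
resolve_class_pars <- function(dr, class_effect) {
  if (is.null(class_effect) || !length(class_effect)) return(character(0))
  out <- vapply(class_effect, function(ce) {
    if (ce %in% dr$pars) return(ce)
    tr <- dr$transforms[[ce]]
    if (!is.null(tr)) return(tr$par)
    stop("unknown class-effect parameter: ", ce)
  }, character(1))
  bad <- setdiff(out, names(dr$class_sd_priors))
  if (length(bad))
    stop("no class-effect SD prior defined for: ", paste(bad, collapse = ", "))
  unique(unname(out))
}

# Arm-level matrices in the ragged-array layout used by the JAGS code.
jags_network_data <- function(net, level) {
  trt <- treatments(net, level = level)
  arms <- net$arms
  node <- arm_node_index(net, trt, level)
  ns <- length(net$studies)
  na <- as.integer(table(factor(arms$study, levels = net$studies)))
  maxa <- max(na)
  M <- function(init) matrix(init, ns, maxa)
  r <- M(NA_real_); n <- M(NA_real_); tmat <- M(NA_integer_)
  agent <- M(NA_integer_); x <- M(NA_real_)
  arm_map <- NULL
  for (i in seq_len(ns)) {
    rows <- which(arms$study == net$studies[i])
    for (k in seq_along(rows)) {
      j <- rows[k]
      r[i, k] <- arms$responders[j]
      n[i, k] <- arms$sample_size[j]
      tmat[i, k] <- node[j]
      agent[i, k] <- match(arms$agent[j], net$agents)
      x[i, k] <- arms$dose_std[j]
    }
    arm_map <- rbind(arm_map,
                     data.frame(study = net$studies[i], i = i,
                                k = seq_along(rows),
                                agent = arms$agent[rows],
                                dose_std = arms$dose_std[rows],
                                responders = arms$responders[rows],
                                sample_size = arms$sample_size[rows],
                                treatment = trt$treatment[node[rows]],
                                stringsAsFactors = FALSE))
  }
  list(data = list(ns = ns, na = na, r = r, n = n, t = tmat, agent = agent,
                   x = x, nt = nrow(trt), nagent = length(net$agents)),
       treatments = trt, arm_map = arm_map)
}

# Index of the free mean for each observed (arm 1, arm k) contrast.  The
# reference-arm tie-break guarantees t[i,1] < t[i,k], so pairs are stored
# ordered; pairs never compared get no parameter.
ume_pairs <- function(dat) {
  d <- dat$data
  pr <- matrix(NA_integer_, d$ns, ncol(d$t))
  seen <- character(0)
  t1 <- integer(0); t2 <- integer(0)
  for (i in seq_len(d$ns)) {
    for (k in 2:d$na[i]) {
      key <- paste(d$t[i, 1], d$t[i, k])
      j <- match(key, seen)
      if (is.na(j)) {
        seen <- c(seen, key); j <- length(seen)
        t1 <- c(t1, d$t[i, 1]); t2 <- c(t2, d$t[i, k])
      }
      pr[i, k] <- j
    }
  }
  tab <- data.frame(contrast = seq_along(seen),
                    treatment1 = dat$treatments$treatment[t1],
                    treatment2 = dat$treatments$treatment[t2],
                    stringsAsFactors = FALSE)
  list(pr = pr, table = tab)
}

build_jags_code <- function(family, effect, dr, priors, class_pars) {
  md <- switch(family,
    lumped = ,
    split = "      md[i,k] <- d[t[i,k]] - d[t[i,1]]",
    ume   = "      md[i,k] <- dd[pr[i,k]]",
    mbnma = "      md[i,k] <- fdr[i,k] - fdr[i,1]")

  fdr <- if (family == "mbnma")
    paste0("    for (k in 1:na[i]) {\n      fdr[i,k] <- ",
           dr$jags_formula, "\n    }\n") else ""

  effect_block <- if (effect == "random") paste0(
    "    w[i,1] <- 0\n",
    "    for (k in 2:na[i]) {\n",
    md, "\n",
    "      delta[i,k] ~ dnorm(mdc[i,k], taud[i,k])\n",
    "      mdc[i,k] <- md[i,k] + sw[i,k]\n",
    "      taud[i,k] <- tau * 2 * (k - 1) / k\n",
    "      w[i,k] <- delta[i,k] - md[i,k]\n",
    "      sw[i,k] <- sum(w[i,1:(k-1)]) / (k - 1)\n",
    "    }\n")
  else paste0(
    "    for (k in 2:na[i]) {\n",
    md, "\n",
    "      delta[i,k] <- md[i,k]\n",
    "    }\n")

  param_block <- switch(family,
    lumped = ,
    split = paste0(
      "  d[1] <- 0\n",
      "  for (k in 2:nt) {\n    d[k] ~ ", priors$effect, "\n  }\n"),
    ume = paste0(
      "  for (j in 1:npair) {\n    dd[j] ~ ", priors$effect, "\n  }\n"),
    mbnma = dr_param_block(dr, priors, class_pars))

  sd_block <- if (effect == "random")
    paste0("  sd ~ ", priors$between_sd, "\n  tau <- pow(sd, -2)\n")
  else ""

  paste0(
    "model {\n",
    "  for (i in 1:ns) {\n",
    "    mu[i] ~ ", priors$mu, "\n",
    "    delta[i,1] <- 0\n",
    "    for (k in 1:na[i]) {\n",
    "      r[i,k] ~ dbin(p[i,k], n[i,k])\n",
    "      logit(p[i,k]) <- mu[i] + delta[i,k]\n",
    "    }\n",
    fdr,
    effect_block,
    "  }\n",
    param_block,
    sd_block,
    "}\n")
}

dr_param_block <- function(dr, priors, class_pars) {
  blocks <- vapply(dr$pars, function(p) {
    if (p %in% class_pars) {
      sd_prior <- priors$class_sd[p]
      if (is.na(sd_prior)) sd_prior <- dr$class_sd_priors[[p]]
      paste0(
        "  ", p, "[1] <- 0\n",
        "  for (a in 2:nagent) {\n",
        "    ", p, "[a] ~ dnorm(m_", p, ", tau_", p, ")\n  }\n",
        "  m_", p, " ~ ", priors$class_mean, "\n",
        "  sd_", p, " ~ ", sd_prior, "\n",
        "  tau_", p, " <- pow(sd_", p, ", -2)\n")
    } else {
      paste0(
        "  ", p, "[1] <- 0\n",
        "  for (a in 2:nagent) {\n",
        "    ", p, "[a] ~ ", priors$effect, "\n  }\n")
    }
  }, character(1))
  paste(blocks, collapse = "")
}

# Overdispersed per-chain starting values: moderate-range draws around the
# prior centres, with the JAGS RNG seeded from the master seed and chain
# index so runs are exactly reproducible.
make_inits <- function(info, dat) {
  d <- dat$data
  function(chain, seed) {
    set.seed((seed %% 100000L) * 31L + chain)
    ini <- list(mu = stats::rnorm(d$ns, 0, 1),
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = (seed %% 100000L) * 100L + chain)
    if (info$family %in% c("lumped", "split"))
      ini$d <- c(NA, stats::rnorm(d$nt - 1, 0, 1))
    if (info$family == "ume")
      ini$dd <- stats::rnorm(d$npair, 0, 1)
    if (info$family == "mbnma") {
      for (p in info$dr$pars)
        ini[[p]] <- c(NA, stats::rnorm(d$nagent - 1, 0, 0.7))
      for (p in info$class_pars) {
        ini[[paste0("m_", p)]] <- stats::rnorm(1, 0, 0.7)
        ini[[paste0("sd_", p)]] <- stats::runif(1, 0.2, 1.5)
      }
    }
    if (info$effect == "random")
      ini$sd <- stats::runif(1, 0.1, 1)
    ini
  }
}

#' @export
print.mbnma_model <- function(x, ...) {
  cat("Unfitted synthesis model: family \"", x$family, "\", ",
      x$effect, " effects", sep = "")
  if (!is.null(x$dose_model))
    cat(", dose-response \"", x$dose_model$name, "\"", sep = "")
  if (length(x$class_pars))
    cat(", exchangeable: ", paste(x$class_pars, collapse = ", "), sep = "")
  cat("\n  studies: ", x$data$ns, ", data points: ", nrow(x$arm_map),
      "\n", sep = "")
  invisible(x)
}
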