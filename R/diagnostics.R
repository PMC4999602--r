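#' Split-chain Gelman-Rubin diagnostic
#'
#' Potential scale reduction factor computed on split chains: each chain's
#' retained draws are halved, doubling the number of sequences, so that
#' trending single chains are caught as well as disagreeing chains.  For a
#' parameter with `m` sequences of length `nh`, with within-sequence
#' variance `W` and between-sequence variance `B`,
#' `Rhat = sqrt(((nh - 1) / nh * W + B / nh) / W)`, floored at 1 so the
#' statistic is always a scale *reduction* factor.  Chains that are
#' identical to one another (zero between-chain information) give exactly
#' 1; constant chains at different values give `Inf`.  Values above 1.05
#' trigger a convergence warning in [mbnma()].
#'
#' @param x a [coda::mcmc.list] (returns one value per parameter) or a
#'   numeric matrix of draws with one column per chain (returns a scalar).
#' @return named numeric vector of Rhat values, each >= 1.
#' @export
split_rhat <- function(x) {
  if (inherits(x, "mcmc.list")) {
    if (length(x) < 2) stop("at least 2 chains are required")
    vars <- coda::varnames(x)
    out <- vapply(vars, function(v) {
      split_rhat(sapply(x, function(ch) as.numeric(ch[, v])))
    }, numeric(1))
    return(out)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("at least 2 chains are required")
  # identical chains carry no between-chain evidence of non-convergence
  if (all(x == x[, 1])) return(1)
  nh <- floor(nrow(x) / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
    cbind(x[seq_len(nh), j], x[nrow(x) - nh + seq_len(nh), j])))
  W <- mean(apply(halves, 2, stats::var))
  B <- nh * stats::var(colMeans(halves))
  if (W == 0) return(Inf)
  sqrt(max(((nh - 1) / nh * W + B / nh) / W, 1))
}

#' Posterior summary table
#'
#' Medians and equal-tailed 95% credible intervals from the pooled
#' post-thinning draws.  Summary transforms are applied draw-wise before
#' taking quantiles (for a monotone transform the two orders agree, but
#' draw-wise application is correct for any transform).  For a fitted
#' model, the dose-response model's declared transforms are added
#' automatically — e.g. ED50 reported on the natural scale alongside the
#' sampled log-ED50 — and parameters are labelled with agent, treatment or
#' contrast names.
#'
#' @param x an [mbnma()] fit or a [coda::mcmc.list].
#' @param transforms named list of extra draw-wise transforms,
#'   `list(<reported name> = list(par = <parameter>, fun = <function>))`;
#'   `par` may be a bare vector name (`"led50"` matches `led50[2]`, ...)
#'   or an exact parameter name.
#' @param probs interval probabilities; default `c(0.025, 0.975)`.
#' @return data.frame with columns `parameter`, `label`, `median`,
#'   `lower`, `upper`.
#' @export
posterior_summary <- function(x, transforms = NULL,
                              probs = c(0.025, 0.975)) {
  if (inherits(x, "mbnma")) {
    fit <- x
    draws <- pooled_draws(fit$samples)
    auto <- if (!is.null(fit$dose_model)) fit$dose_model$transforms else NULL
    transforms <- c(auto, transforms)
    tab <- summarize_draws(draws, transforms, probs)
    tab$label <- label_parameters(tab$parameter, fit)
    return(tab[c("parameter", "label", "median", "lower", "upper")])
  }
  draws <- if (inherits(x, "mcmc.list")) pooled_draws(x) else as.matrix(x)
  tab <- summarize_draws(draws, transforms, probs)
  tab$label <- tab$parameter
  tab[c("parameter", "label", "median", "lower", "upper")]
}

pooled_draws <- function(samples) {
  as.matrix(do.call(rbind, lapply(samples, as.matrix)))
}

summarize_draws <- function(draws, transforms, probs) {
  draws <- as.matrix(draws)
  cols <- colnames(draws)
  for (nm in names(transforms)) {
    tr <- transforms[[nm]]
    hit <- cols[cols == tr$par | grepl(paste0("^", tr$par, "\\["), cols) |
                  cols == paste0("m_", tr$par)]
    for (h in hit) {
      new <- sub(tr$par, nm, h, fixed = TRUE)
      draws <- cbind(draws, tr$fun(draws[, h]))
      colnames(draws)[ncol(draws)] <- new
    }
  }
  qs <- t(apply(draws, 2, stats::quantile,
                probs = c(probs[1], 0.5, probs[2]), names = FALSE))
  data.frame(parameter = colnames(draws), median = qs[, 2],
             lower = qs[, 1], upper = qs[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

label_parameters <- function(pars, fit) {
  agents <- fit$network$agents
  studies <- fit$network$studies
  trts <- fit$treatments$treatment
  vapply(pars, function(p) {
    m <- regmatches(p, regexec("^([a-zA-Z_0-9]+)\\[([0-9]+)\\]$", p))[[1]]
    if (!length(m)) return(p)
    base <- m[2]; idx <- as.integer(m[3])
    switch(base,
           mu = paste0("mu[", studies[idx], "]"),
           d = paste0("d[", trts[idx], "]"),
           dd = if (!is.null(fit$pairs))
             paste0("d[", fit$pairs$treatment2[idx], " vs ",
                    fit$pairs$treatment1[idx], "]") else p,
           paste0(base, "[", agents[idx], "]"))
  }, character(1))
}
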