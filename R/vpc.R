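#' Simulate replicate datasets from a fitted model
#'
#' Posterior-predictive simulation of the fitted trial network: for each
#' replicate a posterior draw is selected, each study's baseline log-odds
#' is taken from that draw, new study-level relative effects are drawn
#' from the between-study distribution (with the multi-arm correlation
#' scheme; fixed-effect fits use the model means directly), and responder
#' counts are drawn from the binomial likelihood.  This is the generative
#' process the model assumes, so the replicates include both between-study
#' and sampling variability.
#'
#' @param object an [mbnma()] fit.
#' @param nsim number of replicate datasets.
#' @param seed seed for the predictive draws.
#' @param ... unused.
#' @return a list of `nsim` data.frames, each the arm table of the fitted
#'   network with simulated `responders`.
#' @export
simulate.mbnma <- function(object, nsim = 1, seed = 1, ...) {
  r_sim <- posterior_predict_arms(object, nsim, seed)
  lapply(seq_len(nsim), function(s) {
    out <- object$arm_map[c("study", "agent", "dose_std", "sample_size")]
    out$responders <- r_sim[s, ]
    out
  })
}

# nsim x npoints matrix of simulated responder counts
posterior_predict_arms <- function(fit, nsim, seed) {
  set.seed(seed)
  md <- arm_md_draws(fit)
  mu <- mu_draws(fit)
  sdd <- sd_draws(fit)
  am <- fit$arm_map
  ndraw <- nrow(md)
  pick <- sample.int(ndraw, nsim, replace = TRUE)
  out <- matrix(NA_real_, nsim, nrow(am))
  for (s in seq_len(nsim)) {
    ds <- pick[s]
    for (i in unique(am$i)) {
      rows <- which(am$i == i)
      means <- md[ds, rows[-1]]
      delta <- if (is.null(sdd)) means
               else rmultiarm_delta(means, sdd[ds])
      p <- stats::plogis(mu[ds, i] + c(0, delta))
      out[s, rows] <- stats::rbinom(length(rows), am$sample_size[rows], p)
    }
  }
  out
}

#' Visual-predictive-check table
#'
#' For every arm of the fitted network, the observed response proportion
#' and the median and 95% interval of the posterior-predictive response
#' proportion (simulated with [simulate.mbnma()], so between-study effects
#' are included).  The table is plot-ready against standardized dose;
#' about 95% of arms should fall inside their intervals when the model
#' fits.
#'
#' @param fit an [mbnma()] fit.
#' @param nsim number of predictive replicates.
#' @param seed seed for the predictive draws.
#' @return data.frame with one row per arm: `study`, `agent`, `dose_std`,
#'   `observed`, `pred_median`, `pred_lower`, `pred_upper`, `inside`.
#' @export
vpc <- function(fit, nsim = 1000, seed = 1) {
  stopifnot(inherits(fit, "mbnma"))
  r_sim <- posterior_predict_arms(fit, nsim, seed)
  am <- fit$arm_map
  prop <- sweep(r_sim, 2, am$sample_size, `/`)
  qs <- t(apply(prop, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
                names = FALSE))
  obs <- am$responders / am$sample_size
  data.frame(study = am$study, agent = am$agent, dose_std = am$dose_std,
             observed = obs, pred_median = qs[, 2], pred_lower = qs[, 1],
             pred_upper = qs[, 3],
             inside = obs >= qs[, 1] & obs <= qs[, 3],
             stringsAsFactors = FALSE)
}
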