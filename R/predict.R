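#' Absolute-response predictions over a dose grid
#'
#' Combines the relative-effect posterior of a synthesis fit with the
#' placebo-anchor posterior of a [placebo_model()] to predict the absolute
#' response probability by agent and standardized dose.  Draw-wise, the
#' prediction is `plogis(anchor + f(x, agent))`: in `"typical"` mode the
#' anchor is the mean of the placebo random-effects distribution (a
#' typical trial); in `"new_trial"` mode a study effect is additionally
#' drawn from that distribution, giving prediction intervals that are at
#' least as wide at every grid point.  The two fits share no parameters,
#' so anchoring cannot feed back into the relative effects; their draw
#' counts are matched by resampling the shorter set with a fixed seed.
#'
#' Dose-response fits predict at any dose (doses beyond the maximum
#' trialed dose of an agent are allowed but flagged as extrapolation);
#' split NMA fits predict only at their trialed (agent, dose) treatments,
#' and lumped NMA fits give one dose-independent prediction per agent.
#'
#' @param object an [mbnma()] fit (any family except `"ume"`).
#' @param placebo a [placebo_model()] fit, or a single log-odds value used
#'   as a fixed anchor.
#' @param doses numeric vector of standardized doses applied to every
#'   active agent, or a named list of per-agent dose vectors; default is
#'   21 points from 0 to each agent's maximum trialed dose (dose-response
#'   fits only).
#' @param mode `"typical"` or `"new_trial"`.
#' @param seed seed for the draw-matching resample and the new-trial
#'   effects.
#' @param ... unused.
#' @return data.frame of class `mbnma_prediction`: `agent`, `dose_std`,
#'   `median`, `lower`, `upper` (95% interval), `extrapolated`, `mode`.
#' @export
predict.mbnma <- function(object, placebo, doses = NULL,
                          mode = c("typical", "new_trial"), seed = 1, ...) {
  mode <- match.arg(mode)
  if (object$model == "ume")
    stop("the unrelated-mean-effects model has no coherent predictions")
  anchor <- placebo_anchor_draws(placebo, mode, seed)

  agents <- setdiff(object$network$agents, object$network$reference)
  max_dose <- vapply(agents, function(a) {
    d <- object$network$arms$dose_std[object$network$arms$agent == a]
    max(d)
  }, numeric(1))

  grid <- prediction_grid(object, agents, doses, max_dose)

  if (object$model == "mbnma") {
    params <- dr_param_draws(object)
    eff <- lapply(seq_len(nrow(grid)), function(j)
      f_draws(object, grid$agent[j], grid$dose_std[j], params))
  } else {
    draws <- pooled_draws(object$samples)
    eff <- lapply(seq_len(nrow(grid)), function(j) {
      tr <- grid$treatment[j]
      draws[, sprintf("d[%d]", match(tr, object$treatments$treatment))]
    })
  }

  set.seed(seed)
  n_eff <- length(eff[[1]])
  n_anc <- length(anchor)
  L <- max(n_eff, n_anc)
  if (n_anc < L) anchor <- anchor[sample.int(n_anc, L, replace = TRUE)]
  idx_eff <- if (n_eff < L) sample.int(n_eff, L, replace = TRUE)
             else seq_len(n_eff)

  qs <- t(vapply(eff, function(e) {
    p <- stats::plogis(anchor + e[idx_eff])
    stats::quantile(p, c(0.025, 0.5, 0.975), names = FALSE)
  }, numeric(3)))

  out <- data.frame(agent = grid$agent, dose_std = grid$dose_std,
                    median = qs[, 2], lower = qs[, 1], upper = qs[, 3],
                    extrapolated = !is.na(grid$dose_std) &
                      grid$dose_std > max_dose[grid$agent],
                    mode = mode, stringsAsFactors = FALSE)
  class(out) <- c("mbnma_prediction", "data.frame")
  out
}

placebo_anchor_draws <- function(placebo, mode, seed) {
  if (is.numeric(placebo) && length(placebo) == 1) {
    if (mode == "new_trial")
      stop("new-trial predictions need a fitted placebo model")
    return(placebo)
  }
  stopifnot(inherits(placebo, "mbnma_placebo"))
  draws <- pooled_draws(placebo$samples)
  m <- draws[, "m"]
  if (mode == "typical") return(m)
  set.seed(seed + 1L)
  m + stats::rnorm(length(m), 0, draws[, "sdp"])
}

prediction_grid <- function(fit, agents, doses, max_dose) {
  if (fit$model == "lumped") {
    return(data.frame(agent = agents, dose_std = NA_real_,
                      treatment = agents, stringsAsFactors = FALSE))
  }
  if (fit$model == "split") {
    trt <- fit$treatments
    trt <- trt[trt$agent != fit$network$reference, , drop = FALSE]
    return(data.frame(agent = trt$agent, dose_std = trt$dose_std,
                      treatment = trt$treatment, stringsAsFactors = FALSE))
  }
  if (is.null(doses))
    doses <- lapply(agents, function(a)
      seq(0, max_dose[a], length.out = 21))
  if (is.numeric(doses)) doses <- stats::setNames(
    rep(list(doses), length(agents)), agents)
  if (is.null(names(doses))) {
    if (length(doses) != length(agents))
      stop("unnamed dose lists must have one element per active agent")
    names(doses) <- agents
  }
  bad <- setdiff(names(doses), agents)
  if (length(bad)) stop("agent absent from fit: ", paste(bad, collapse = ", "))
  do.call(rbind, lapply(names(doses), function(a)
    data.frame(agent = a, dose_std = doses[[a]], treatment = NA_character_,
               stringsAsFactors = FALSE)))
}

#' @export
print.mbnma_prediction <- function(x, ...) {
  cat("Predicted response probabilities (", x$mode[1], " trial)\n",
      sep = "")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot fitted dose-response curves or predictions
#'
#' For a dose-response fit, plots the posterior-median relative effect
#' f(x, agent) on the log-odds scale over the trialed dose range of each
#' agent (base graphics; one line per agent).  For other families, plots
#' the posterior medians and credible intervals of the basic parameters.
#'
#' @param x an [mbnma()] fit.
#' @param n_points grid resolution per agent.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mbnma <- function(x, n_points = 50, ...) {
  if (x$model == "mbnma") {
    agents <- setdiff(x$network$agents, x$network$reference)
    xmax <- max(x$network$arms$dose_std)
    gx <- seq(0, xmax, length.out = n_points)
    params <- dr_param_draws(x)
    curves <- vapply(agents, function(a)
      vapply(gx, function(d) stats::median(f_draws(x, a, d, params)),
             numeric(1)),
      numeric(n_points))
    graphics::matplot(gx, curves, type = "l", lty = 1,
                      xlab = "standardized dose",
                      ylab = "relative effect (log-odds)", ...)
    graphics::legend("bottomright", legend = agents, lty = 1,
                     col = seq_along(agents), bty = "n")
  } else {
    tab <- x$summary
    rows <- grepl("^(d|dd)\\[", tab$parameter)
    tab <- tab[rows, , drop = FALSE]
    graphics::plot(tab$median, seq_len(nrow(tab)), xlim =
                     range(tab$lower, tab$upper),
                   yaxt = "n", xlab = "log-odds ratio", ylab = "",
                   pch = 16, ...)
    graphics::segments(tab$lower, seq_len(nrow(tab)), tab$upper,
                       seq_len(nrow(tab)))
    graphics::axis(2, at = seq_len(nrow(tab)), labels = tab$label,
                   las = 1, cex.axis = 0.7)
    graphics::abline(v = 0, lty = 3)
  }
  invisible(x)
}
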