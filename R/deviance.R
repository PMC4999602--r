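#' Residual deviance of binomial arms
#'
#' Saturated-versus-fitted binomial deviance contribution of each arm:
#' `2 [ r log(r / (n p)) + (n - r) log((n - r) / (n - n p)) ]`, with the
#' convention `0 log 0 = 0` at boundary counts.  Under a well-specified
#' model each arm is expected to contribute about 1.
#'
#' @param r responders per arm.
#' @param n sample size per arm.
#' @param p_hat fitted probability per arm, strictly inside (0, 1); a
#'   fitted probability of exactly 0 or 1 signals a degenerate fit and is
#'   an error.
#' @return numeric vector of non-negative contributions.
#' @export
binomial_residual_deviance <- function(r, n, p_hat) {
  stopifnot(length(r) == length(n), length(p_hat) == length(r))
  if (any(p_hat <= 0) || any(p_hat >= 1))
    stop("fitted probabilities must lie strictly in (0, 1)")
  if (any(r < 0) || any(r > n))
    stop("responders must lie in [0, sample_size]")
  xlogx <- function(x) ifelse(x == 0, 0, x * log(x))
  2 * (xlogx(r) - r * log(n * p_hat) +
         xlogx(n - r) - (n - r) * log(n - n * p_hat))
}

#' Normal residual deviance
#'
#' Contribution `((y - theta) / se)^2` per data point, for
#' known-standard-error normal likelihoods.
#'
#' @param y observed values.
#' @param theta fitted means.
#' @param se known standard errors.
#' @return numeric vector of contributions.
#' @export
normal_residual_deviance <- function(y, theta, se) {
  ((y - theta) / se)^2
}

#' Plug-in DIC from posterior draws of fitted values
#'
#' Computes the deviance report used throughout the package: the posterior
#' mean total residual deviance `Dbar`, the deviance at the plug-in
#' (posterior-mean) fitted values `D_plugin`, the plug-in effective number
#' of parameters `pD = Dbar - D_plugin`, and `DIC = Dbar + pD`.  The
#' plug-in point is the posterior mean of the fitted probabilities on the
#' probability scale (for the binomial family), which pairs directly with
#' the residual-deviance formula; sampler-reported effective-parameter
#' counts are known to be unreliable for the nonlinear models fitted here,
#' hence the explicit plug-in construction.  A single posterior draw gives
#' `pD = 0` exactly; a negative `pD` raises a warning rather than being
#' silently accepted.
#'
#' @param fitted_draws matrix of posterior draws (rows) of the fitted
#'   value of each data point (columns): probabilities for
#'   `family = "binomial"`, means for `family = "normal"`.
#' @param observed observed responder counts (binomial) or values
#'   (normal).
#' @param family `"binomial"` or `"normal"`.
#' @param n sample sizes (binomial only).
#' @param se known standard errors (normal only).
#' @param labels optional data.frame of per-point labels bound onto the
#'   per-point table.
#' @return an object of class `deviance_report`: list with `Dbar`,
#'   `D_plugin`, `pD`, `DIC`, `per_point` (data.frame of posterior-mean
#'   contributions, summing to `Dbar`) and `n_datapoints`.
#' @export
plugin_dic <- function(fitted_draws, observed,
                       family = c("binomial", "normal"),
                       n = NULL, se = NULL, labels = NULL) {
  family <- match.arg(family)
  fitted_draws <- as.matrix(fitted_draws)
  np <- ncol(fitted_draws)
  stopifnot(length(observed) == np)

  # one deviance path for both the per-draw totals and the plug-in point,
  # so a single-draw "posterior" gives pD = 0 exactly
  if (family == "binomial") {
    stopifnot(!is.null(n), length(n) == np)
    if (any(fitted_draws <= 0) || any(fitted_draws >= 1))
      stop("fitted probabilities must lie strictly in (0, 1)")
    dev_fun <- function(fd) {
      xlogx <- function(x) ifelse(x == 0, 0, x * log(x))
      const <- xlogx(observed) + xlogx(n - observed) - n * log(n)
      out <- 2 * (rep(const, each = nrow(fd)) -
                    sweep(log(fd), 2, observed, `*`) -
                    sweep(log1p(-fd), 2, n - observed, `*`))
      dim(out) <- dim(fd)
      out
    }
  } else {
    stopifnot(!is.null(se), length(se) == np)
    dev_fun <- function(fd)
      sweep(sweep(fd, 2, observed, `-`), 2, se, `/`)^2
  }
  dev_draws <- dev_fun(fitted_draws)
  plug <- colMeans(fitted_draws)
  D_plugin <- sum(dev_fun(matrix(plug, nrow = 1)))

  per_point <- colMeans(dev_draws)
  Dbar <- sum(per_point)
  pD <- Dbar - D_plugin
  if (pD < 0)
    warning("negative plug-in pD (", format(pD, digits = 3),
            "); the plug-in point may be unrepresentative")
  pp <- data.frame(contribution = per_point)
  if (family == "binomial") {
    pp$responders <- observed
    pp$sample_size <- n
  } else {
    pp$observed <- observed
    pp$se <- se
  }
  if (!is.null(labels)) pp <- cbind(as.data.frame(labels), pp)
  structure(list(Dbar = Dbar, D_plugin = D_plugin, pD = pD,
                 DIC = Dbar + pD, per_point = pp, n_datapoints = np),
            class = "deviance_report")
}

#' @export
print.deviance_report <- function(x, ...) {
  cat("Residual deviance report (", x$n_datapoints, " data points)\n",
      sep = "")
  cat(sprintf("  Dbar = %.2f  D(plug-in) = %.2f  pD = %.2f  DIC = %.2f\n",
              x$Dbar, x$D_plugin, x$pD, x$DIC))
  cat(sprintf("  mean contribution per data point: %.3f\n",
              x$Dbar / x$n_datapoints))
  invisible(x)
}

#' Deviance report of a fitted model
#'
#' @param fit an [mbnma()] fit.
#' @return the fit's `deviance_report`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "mbnma"))
  fit$deviance
}

#' Compare fitted synthesis models
#'
#' Tabulates model-fit statistics for any number of fits of the same
#' dataset: plug-in DIC, effective parameters pD, posterior mean residual
#' deviance, and the between-study SD median with 95% credible interval
#' (random-effects fits only).  Rows are sorted by DIC; DIC differences
#' below 3 are flagged as not meaningfully different.
#'
#' @param ... named [mbnma()] fits on the same dataset.
#' @return data.frame of class `mbnma_comparison` with attributes
#'   `close_pairs` (pairs of models within 3 DIC units).
#' @export
compare_fits <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "mbnma"))
    fits <- fits[[1]]
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "mbnma")))
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- vapply(fits, function(f)
      paste0(f$model, if (!is.null(f$dose_model))
        paste0(":", f$dose_model$name)), character(1))
  sigs <- vapply(fits, function(f) f$data_sig, character(1))
  if (length(unique(sigs)) > 1)
    stop("fits are not all on the same dataset")
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    sd_row <- f$summary[f$summary$parameter == "sd", , drop = FALSE]
    data.frame(model = nm, DIC = f$deviance$DIC, pD = f$deviance$pD,
               resdev = f$deviance$Dbar,
               sd_median = if (nrow(sd_row)) sd_row$median else NA_real_,
               sd_lower = if (nrow(sd_row)) sd_row$lower else NA_real_,
               sd_upper = if (nrow(sd_row)) sd_row$upper else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$DIC), , drop = FALSE]
  rownames(tab) <- NULL
  close <- NULL
  if (nrow(tab) > 1) {
    cmb <- utils::combn(nrow(tab), 2)
    near <- abs(tab$DIC[cmb[1, ]] - tab$DIC[cmb[2, ]]) < 3
    if (any(near))
      close <- data.frame(model1 = tab$model[cmb[1, near]],
                          model2 = tab$model[cmb[2, near]],
                          dDIC = abs(tab$DIC[cmb[1, near]] -
                                       tab$DIC[cmb[2, near]]))
  }
  structure(tab, close_pairs = close,
            class = c("mbnma_comparison", "data.frame"))
}

#' @export
print.mbnma_comparison <- function(x, ...) {
  cat("Model comparison (sorted by plug-in DIC; differences >= 3 are",
      "meaningful):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cp <- attr(x, "close_pairs")
  if (!is.null(cp) && nrow(cp))
    for (i in seq_len(nrow(cp)))
      cat(sprintf("  %s vs %s: dDIC = %.2f, not meaningfully different\n",
                  cp$model1[i], cp$model2[i], cp$dDIC[i]))
  invisible(x)
}

#' Screen for evidence inconsistency against a UME model
#'
#' Compares a consistency model (split NMA or model-based NMA) with an
#' unrelated-mean-effects fit of the same split-coded data.  Reports the
#' paired per-point posterior-mean deviance contributions and their
#' differences (points fitting substantially worse under the consistency
#' model point to the inconsistent loops), the two between-study SD
#' posteriors side by side, and the DIC difference.
#'
#' Because the UME model relaxes consistency, genuine inconsistency
#' inflates the consistency model's between-study SD but not the UME's.
#' Two flags are returned: `flag_median`, the bare comparison of posterior
#' medians (UME below consistency), and `flag`, which requires
#' `Pr(sd_UME < sd_consistency) >= prob` computed by pairing the two
#' fits' independent posterior draws.  The bare median comparison is close
#' to a coin flip when the data are consistent, so the probability flag
#' (default threshold 0.8) is the calibrated screen.
#'
#' @param consistency_fit a random-effects [mbnma()] fit of a consistency
#'   model on split-coded data.
#' @param ume_fit a random-effects [mbnma()] fit with `model = "ume"` on
#'   the same data.
#' @param prob posterior-probability threshold for the calibrated flag.
#' @return object of class `inconsistency_check`: list with `per_point`
#'   (paired deviance table), `sd` (summary of both SD posteriors),
#'   `p_ume_lower`, `flag`, `flag_median`, `dDIC`.
#' @export
inconsistency_check <- function(consistency_fit, ume_fit, prob = 0.8) {
  stopifnot(inherits(consistency_fit, "mbnma"), inherits(ume_fit, "mbnma"))
  if (ume_fit$model != "ume")
    stop("ume_fit must be an unrelated-mean-effects fit")
  if (consistency_fit$data_sig != ume_fit$data_sig)
    stop("fits are not on the same data points")
  if (consistency_fit$effect != "random" || ume_fit$effect != "random")
    stop("the between-study SD screen needs random-effects fits")

  ppc <- consistency_fit$deviance$per_point
  ppu <- ume_fit$deviance$per_point
  per_point <- data.frame(ppc[c("study", "agent", "dose_std")],
                          dev_consistency = ppc$contribution,
                          dev_ume = ppu$contribution,
                          difference = ppc$contribution - ppu$contribution)

  sd_c <- pooled_draws(consistency_fit$samples)[, "sd"]
  sd_u <- pooled_draws(ume_fit$samples)[, "sd"]
  m <- min(length(sd_c), length(sd_u))
  p_lower <- mean(sd_u[seq_len(m)] < sd_c[seq_len(m)])
  sd_tab <- data.frame(
    model = c("consistency", "ume"),
    median = c(stats::median(sd_c), stats::median(sd_u)),
    lower = c(stats::quantile(sd_c, 0.025), stats::quantile(sd_u, 0.025)),
    upper = c(stats::quantile(sd_c, 0.975), stats::quantile(sd_u, 0.975)),
    row.names = NULL)

  structure(list(per_point = per_point, sd = sd_tab,
                 p_ume_lower = p_lower,
                 flag = p_lower >= prob,
                 flag_median = sd_tab$median[2] < sd_tab$median[1],
                 prob = prob,
                 dDIC = consistency_fit$deviance$DIC - ume_fit$deviance$DIC),
            class = "inconsistency_check")
}

#' @export
print.inconsistency_check <- function(x, ...) {
  cat("Inconsistency screen (consistency model vs unrelated mean",
      "effects)\n")
  cat("Between-study SD posteriors:\n")
  print(x$sd, row.names = FALSE, digits = 3)
  cat(sprintf("Pr(sd_UME < sd_consistency) = %.3f -> %s (threshold %.2f)\n",
              x$p_ume_lower,
              if (x$flag) "INCONSISTENCY FLAGGED" else "no flag", x$prob))
  cat(sprintf("DIC(consistency) - DIC(UME) = %.2f\n", x$dDIC))
  worst <- x$per_point[order(-x$per_point$difference), ][1:min(5,
    nrow(x$per_point)), ]
  cat("Largest consistency-model deviance excesses:\n")
  print(worst, row.names = FALSE, digits = 3)
  invisible(x)
}
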