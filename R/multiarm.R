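#' Multi-arm random-effects decomposition
#'
#' In a random-effects synthesis the study-level relative effects of an
#' a-arm trial (arms 2..a versus arm 1) are exchangeable multivariate
#' normal with common variance sigma^2 and covariance sigma^2 / 2.  Gibbs
#' samplers realize this joint distribution through sequential univariate
#' conditionals: counting arms j = 2..a, the j-th relative effect has
#'
#' * conditional mean `m_j + sum_{h<j} (delta_h - m_h) / (j - 1)`, and
#' * conditional variance `sigma^2 * j / (2 (j - 1))`,
#'
#' where `m_j` is the model mean of the j-th effect.  For a two-arm study
#' this reduces to a plain normal with variance sigma^2.
#' `rmultiarm_delta` draws one study's effects through this scheme and
#' `dmultiarm_delta` evaluates its joint density, which equals the
#' multivariate-normal density exactly.
#'
#' @param means numeric vector of model means, one per non-reference arm
#'   (length a - 1).
#' @param sigma between-study SD (common to all contrasts).
#' @param delta numeric vector of realized relative effects, same length
#'   as `means`.
#' @param log logical; return the log density.
#' @return `rmultiarm_delta`: a numeric vector of relative effects;
#'   `dmultiarm_delta`: the (log) joint density.
#' @name multiarm
NULL

#' @rdname multiarm
#' @export
rmultiarm_delta <- function(means, sigma) {
  p <- length(means)
  stopifnot(p >= 1, sigma >= 0)
  delta <- numeric(p)
  for (j in seq_len(p)) {
    arm <- j + 1  # j-th relative effect belongs to arm j+1
    cond_mean <- means[j] +
      if (j > 1) sum(delta[1:(j - 1)] - means[1:(j - 1)]) / (arm - 1) else 0
    cond_var <- sigma^2 * arm / (2 * (arm - 1))
    delta[j] <- stats::rnorm(1, cond_mean, sqrt(cond_var))
  }
  delta
}

#' @rdname multiarm
#' @export
dmultiarm_delta <- function(delta, means, sigma, log = TRUE) {
  p <- length(means)
  stopifnot(length(delta) == p, p >= 1, sigma > 0)
  ld <- 0
  for (j in seq_len(p)) {
    arm <- j + 1
    cond_mean <- means[j] +
      if (j > 1) sum(delta[1:(j - 1)] - means[1:(j - 1)]) / (arm - 1) else 0
    cond_var <- sigma^2 * arm / (2 * (arm - 1))
    ld <- ld + stats::dnorm(delta[j], cond_mean, sqrt(cond_var), log = TRUE)
  }
  if (log) ld else exp(ld)
}
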