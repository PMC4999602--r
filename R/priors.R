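#' Prior specification
#'
#' Priors are given as JAGS distribution strings.  The defaults are the
#' vague priors conventional for binomial-logit network meta-analysis:
#' normal with mean 0 and variance 1000 (precision 0.001) on relative
#' effects, dose-response parameters and the study nuisance baselines, and
#' uniform(0, 4) on the between-study SD of log-odds ratios.  A half-normal
#' with precision 100 on the SD is a common sensitivity alternative; use
#' [prior_half_normal()].  Class-effect (exchangeability) means default to
#' the same vague normal; class-effect SD priors live on the
#' [dose_response()] object because sensible widths are parameter-specific.
#'
#' @param effect prior for basic relative-effect parameters and per-agent
#'   dose-response parameters.
#' @param mu prior for the study baseline (arm-1 log-odds) nuisance
#'   parameters, always independent across studies so that concurrent
#'   control is respected.
#' @param between_sd prior for the common between-study SD.
#' @param class_mean prior for class-effect means.
#' @param class_sd named character vector overriding the dose-response
#'   model's class-effect SD priors (names are parameter names); empty to
#'   keep the model's defaults.
#' @return an object of class `mbnma_priors`.
#' @examples
#' mbnma_priors(between_sd = prior_half_normal(100))
#' @export
mbnma_priors <- function(effect = "dnorm(0, 0.001)",
                         mu = "dnorm(0, 0.001)",
                         between_sd = "dunif(0, 4)",
                         class_mean = "dnorm(0, 0.001)",
                         class_sd = character(0)) {
  stopifnot(is.character(effect), is.character(mu),
            is.character(between_sd), is.character(class_mean))
  structure(list(effect = effect, mu = mu, between_sd = between_sd,
                 class_mean = class_mean, class_sd = class_sd),
            class = "mbnma_priors")
}

#' Half-normal prior string for a standard deviation
#'
#' @param precision precision of the underlying normal; the default 100
#'   gives a half-normal with SD 0.1 on the positive reals.
#' @return a JAGS prior string, truncated to positive support.
#' @export
prior_half_normal <- function(precision = 100) {
  sprintf("dnorm(0, %g) T(0,)", precision)
}
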