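#' Define a dose-response model
#'
#' A dose-response model gives the contribution f(x, t) of agent t at
#' standardized dose x to the linear predictor (log-odds scale).  Relative
#' effects between arms are differences of f, which makes every contrast a
#' function of the per-agent parameters and enforces evidence consistency
#' by construction.  The network reference (placebo) contributes f = 0
#' exactly; every model must satisfy f(0, t) = 0 or document the
#' discontinuity (the linear model with intercept does not vanish as the
#' dose falls to zero).
#'
#' Custom models registered with [register_dose_response()] drop into
#' [mbnma()] by name with no other change.  The JAGS formula must define
#' the arm-level node in terms of per-agent parameter vectors indexed by
#' `agent[i,k]` and the dose matrix `x[i,k]`; element 1 of each parameter
#' vector belongs to the reference agent and is fixed to 0.
#'
#' @param name model name used for registry lookup.
#' @param pars character vector of per-agent parameter names (as used in
#'   the JAGS code).
#' @param fun R function `(x, theta)` evaluating f for one agent; `theta`
#'   is a named vector (or, for draw-wise evaluation, a named list of
#'   equal-length vectors) with the elements of `pars`; access elements
#'   with `theta[["name"]]` so both cases work.
#' @param jags_formula JAGS expression for f of arm (i, k), e.g.
#'   `"emax[agent[i,k]] * x[i,k] / (exp(led50[agent[i,k]]) + x[i,k])"`.
#' @param class_sd_priors named character of JAGS prior strings for the
#'   exchangeability (class-effect) SD of each parameter that may be made
#'   exchangeable across agents; parameters not listed cannot carry a class
#'   effect.
#' @param transforms named list of draw-wise summary transforms; each
#'   element is `list(par = <sampled parameter>, fun = <function>)` and its
#'   name becomes the reported parameter (e.g.
#'   `list(ed50 = list(par = "led50", fun = exp))` reports ED50 on the
#'   natural scale).
#' @return an object of class `dose_response`.
#' @examples
#' # the built-in Emax model
#' dr <- dr_emax()
#' dr$fun(1, c(emax = 2, led50 = 0))  # half-maximal effect: 1
#' @export
dose_response <- function(name, pars, fun, jags_formula,
                          class_sd_priors = character(0),
                          transforms = list()) {
  stopifnot(is.character(name), length(name) == 1, is.function(fun),
            is.character(pars), length(pars) >= 1)
  structure(list(name = name, pars = pars, fun = fun,
                 jags_formula = jags_formula,
                 class_sd_priors = class_sd_priors,
                 transforms = transforms),
            class = "dose_response")
}

#' Emax dose-response model
#'
#' f(x, t) = Emax_t x / (ED50_t + x) on the log-odds scale.  Emax_t is the
#' asymptotic maximum effect of agent t relative to placebo
#' (sign-unconstrained, so harmful effects are allowed) and ED50_t the
#' standardized dose at which half that effect is reached.  ED50 is a dose
#' and therefore positive, so it is parameterized as `led50 = log(ED50)`
#' in the sampler and in class-effect hierarchies; summaries back-transform
#' to the natural scale.
#'
#' The default class-effect SD priors are uniform(0, 20) for the Emax SD
#' and uniform(0, 4) for the log-ED50 SD: the wider prior on the Emax SD
#' avoids pinning a parameter that is often weakly identified.
#'
#' @return a [dose_response()] object named `"emax"` with per-agent
#'   parameters `emax` and `led50`.
#' @export
dr_emax <- function() {
  dose_response(
    name = "emax",
    pars = c("emax", "led50"),
    fun = function(x, theta) {
      theta[["emax"]] * x / (exp(theta[["led50"]]) + x)
    },
    jags_formula =
      "emax[agent[i,k]] * x[i,k] / (exp(led50[agent[i,k]]) + x[i,k])",
    class_sd_priors = c(emax = "dunif(0, 20)", led50 = "dunif(0, 4)"),
    transforms = list(ed50 = list(par = "led50", fun = exp))
  )
}

#' Linear dose-response model
#'
#' f(x, t) = d_t x, or b_t + d_t x with an intercept, on the log-odds
#' scale.  The intercept is defined only for active agents (placebo remains
#' the fixed zero of the scale), so the with-intercept model is
#' discontinuous as the dose of an active agent falls to zero; it can be
#' read as absorbing nonlinearity near zero dose.
#'
#' @param intercept logical; include the per-agent intercept b_t.
#' @return a [dose_response()] object named `"linear"` or
#'   `"linear_intercept"`.
#' @export
dr_linear <- function(intercept = FALSE) {
  if (intercept) {
    dose_response(
      name = "linear_intercept",
      pars = c("b", "slope"),
      fun = function(x, theta) theta[["b"]] + theta[["slope"]] * x,
      jags_formula = "b[agent[i,k]] + slope[agent[i,k]] * x[i,k]",
      class_sd_priors = c(b = "dunif(0, 4)", slope = "dunif(0, 4)"))
  } else {
    dose_response(
      name = "linear",
      pars = "slope",
      fun = function(x, theta) theta[["slope"]] * x,
      jags_formula = "slope[agent[i,k]] * x[i,k]",
      class_sd_priors = c(slope = "dunif(0, 4)"))
  }
}

.dr_registry <- new.env(parent = emptyenv())

#' Register a dose-response model by name
#'
#' @param model a [dose_response()] object.
#' @return the model, invisibly.
#' @export
register_dose_response <- function(model) {
  stopifnot(inherits(model, "dose_response"))
  assign(model$name, model, envir = .dr_registry)
  invisible(model)
}

#' Look up a dose-response model
#'
#' @param model a model name (`"emax"`, `"linear"`, `"linear_intercept"`,
#'   or a registered custom name) or a [dose_response()] object, returned
#'   as is.
#' @return a [dose_response()] object.
#' @export
get_dose_response <- function(model) {
  if (inherits(model, "dose_response")) return(model)
  stopifnot(is.character(model), length(model) == 1)
  if (!exists(model, envir = .dr_registry)) {
    builtin <- switch(model,
                      emax = dr_emax(),
                      linear = dr_linear(FALSE),
                      linear_intercept = dr_linear(TRUE),
                      NULL)
    if (is.null(builtin))
      stop("unknown dose-response model: ", model)
    register_dose_response(builtin)
  }
  get(model, envir = .dr_registry)
}

# Evaluate f for one arm; the reference agent contributes exactly 0.
dr_value <- function(dr, agent, x, params, reference) {
  if (agent == reference) return(0)
  if (!agent %in% names(params)) stop("unknown agent: ", agent)
  dr$fun(x, params[[agent]])
}

#' Relative effect implied by a dose-response model
#'
#' The log-odds ratio of arm k versus arm 1 of a study is
#' f(x_k, t_k) - f(x_1, t_1).  Because every contrast is such a
#' difference, the consistency relation d(c,k) = d(1,k) - d(1,c) holds
#' identically for any parameter values.
#'
#' @param dr a [dose_response()] object or model name.
#' @param agent_k,dose_k agent label and standardized dose of the
#'   comparator arm.
#' @param agent_1,dose_1 agent label and standardized dose of the
#'   reference arm.
#' @param params named list: per active agent, a named parameter vector
#'   (e.g. `list(drugA = c(emax = 2, led50 = 0))`).
#' @param reference reference agent label, which contributes f = 0.
#' @return the relative effect on the log-odds scale.
#' @export
relative_effect <- function(dr, agent_k, dose_k, agent_1, dose_1, params,
                            reference = "placebo") {
  dr <- get_dose_response(dr)
  dr_value(dr, agent_k, dose_k, params, reference) -
    dr_value(dr, agent_1, dose_1, params, reference)
}

#' @export
print.dose_response <- function(x, ...) {
  cat("Dose-response model \"", x$name, "\"\n", sep = "")
  cat("  per-agent parameters: ", paste(x$pars, collapse = ", "), "\n",
      sep = "")
  cat("  f(x) = ", x$jags_formula, "\n", sep = "")
  invisible(x)
}
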