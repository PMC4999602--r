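#' Specify the true data-generating process for a simulated network
#'
#' Defines the ground truth and study layout for [simulate_network()].
#' The defaults emulate the structure of a typical analgesic trial
#' network: a single placebo hub to which most evidence is anchored, a
#' handful of active agents each trialed at several multiples of its
#' common dose, some three-arm trials (so the multi-arm correlation is
#' exercised), and a few head-to-head trials at the common dose — with
#' the first two agents compared head-to-head most often, as market
#' leaders tend to be.  Truth defaults: Emax dose-response with per-agent
#' maximum effects 1.0, 1.5, 2.0, 2.5 log-odds and ED50 equal to the
#' common dose; between-study SD 0.25; placebo log-odds distributed
#' normal(-1.5, 0.3^2); 40 studies of 200 subjects per arm.
#'
#' @param agents character vector of active-agent names.
#' @param dose_model dose-response model name or [dose_response()] object
#'   used as truth.
#' @param params named list of per-parameter numeric vectors, one element
#'   per agent in order (e.g. `list(emax = c(...), led50 = c(...))`).
#' @param sigma true between-study SD of log-odds ratios.
#' @param placebo_mean,placebo_sd mean and SD of the study baseline
#'   (arm-1) log-odds distribution.
#' @param n_studies total number of studies.
#' @param n_per_arm subjects per arm.
#' @param doses standardized doses allocated to placebo-controlled trials
#'   (cycled over agent-dose combinations so every combination is
#'   covered); head-to-head and three-arm trials use dose 1.
#' @param prop_three_arm,prop_head_to_head fractions of studies that are
#'   three-arm (placebo + two agents) and two-arm head-to-head.
#' @param reference reference (placebo) agent name.
#' @return an object of class `network_truth`.
#' @export
network_truth <- function(agents = paste0("drug", LETTERS[1:4]),
                          dose_model = "emax",
                          params = list(emax = c(1.0, 1.5, 2.0, 2.5),
                                        led50 = c(0, 0, 0, 0)),
                          sigma = 0.25,
                          placebo_mean = -1.5, placebo_sd = 0.3,
                          n_studies = 40, n_per_arm = 200,
                          doses = c(0.25, 0.5, 1, 2, 4),
                          prop_three_arm = 0.15,
                          prop_head_to_head = 0.15,
                          reference = "placebo") {
  dr <- get_dose_response(dose_model)
  stopifnot(setequal(names(params), dr$pars),
            all(lengths(params) == length(agents)),
            sigma >= 0, placebo_sd >= 0, n_studies >= 2, n_per_arm >= 1,
            all(doses > 0),
            prop_three_arm >= 0, prop_head_to_head >= 0,
            prop_three_arm + prop_head_to_head < 1)
  structure(list(agents = agents, dose_model = dr, params = params,
                 sigma = sigma, placebo_mean = placebo_mean,
                 placebo_sd = placebo_sd, n_studies = n_studies,
                 n_per_arm = n_per_arm, doses = doses,
                 prop_three_arm = prop_three_arm,
                 prop_head_to_head = prop_head_to_head,
                 reference = reference),
            class = "network_truth")
}

# Deterministic study layout: which agents and doses each study compares.
# Randomness enters only through baselines, study effects and binomial
# outcomes, so connectivity is guaranteed by construction.
truth_layout <- function(truth) {
  n3 <- round(truth$prop_three_arm * truth$n_studies)
  nh <- round(truth$prop_head_to_head * truth$n_studies)
  n2 <- truth$n_studies - n3 - nh
  A <- length(truth$agents)
  # agent varies fastest so even small layouts spread over all agents
  combos <- expand.grid(agent = truth$agents, dose = truth$doses,
                        stringsAsFactors = FALSE)
  layout <- vector("list", truth$n_studies)
  s <- 0
  for (j in seq_len(n2)) {
    cmb <- combos[(j - 1) %% nrow(combos) + 1, ]
    s <- s + 1
    layout[[s]] <- data.frame(agent = c(truth$reference, cmb$agent),
                              dose_std = c(0, cmb$dose))
  }
  for (j in seq_len(n3)) {
    a1 <- (j - 1) %% A + 1
    a2 <- a1 %% A + 1
    s <- s + 1
    layout[[s]] <- data.frame(
      agent = c(truth$reference, truth$agents[a1], truth$agents[a2]),
      dose_std = c(0, 1, 1))
  }
  for (j in seq_len(nh)) {
    # market-leader pattern: most head-to-head evidence on agents 1 vs 2
    if (A < 2) stop("head-to-head studies need at least 2 agents")
    if (j <= ceiling(2 * nh / 3) || A == 2) {
      pair <- c(1, 2)
    } else {
      k <- (j - 1) %% (A - 1) + 1
      pair <- c(k, k + 1)
    }
    s <- s + 1
    layout[[s]] <- data.frame(agent = truth$agents[pair],
                              dose_std = c(1, 1))
  }
  names(layout) <- sprintf("study%02d", seq_len(truth$n_studies))
  used <- unique(unlist(lapply(layout, `[[`, "agent")))
  missing <- setdiff(truth$agents, used)
  if (length(missing))
    stop("infeasible layout: no arms allocated to ",
         paste(missing, collapse = ", "))
  layout
}

#' Simulate a trial network with known truth
#'
#' Runs the model forward: per study, a baseline log-odds is drawn from
#' the placebo distribution, study-level relative effects are drawn
#' around the dose-response means through the multi-arm correlation
#' scheme ([rmultiarm_delta()]), and responder counts are binomial.  Each
#' study uses a sub-seed derived from the master seed, so regenerating a
#' subset of studies (see [inject_inconsistency()]) leaves all other
#' studies byte-identical.
#'
#' @param truth a [network_truth()] specification.
#' @param seed master seed; the same seed reproduces the dataset exactly.
#' @return a [dose_network()] (standardized doses) with attribute
#'   `"truth"`: a list recording the specification, seed, layout and the
#'   realized study effects.
#' @export
simulate_network <- function(truth = network_truth(), seed = 1) {
  stopifnot(inherits(truth, "network_truth"))
  layout <- truth_layout(truth)
  arms <- do.call(rbind, lapply(seq_along(layout), function(i)
    simulate_study(truth, layout, i, seed)))
  net <- dose_network(arms, reference = truth$reference,
                      standardized = TRUE)
  attr(net, "truth") <- list(truth = truth, seed = seed, layout = layout)
  net
}

study_seed <- function(seed, i) (abs(seed) + 7919L * i) %% 2147483647L

simulate_study <- function(truth, layout, i, seed, offset = 0,
                           offset_agent = NULL) {
  set.seed(study_seed(seed, i))
  arms <- layout[[i]]
  params <- lapply(seq_along(truth$agents), function(a)
    vapply(truth$params, `[`, numeric(1), a))
  names(params) <- truth$agents
  fvals <- vapply(seq_len(nrow(arms)), function(k)
    dr_value(truth$dose_model, arms$agent[k], arms$dose_std[k], params,
             truth$reference), numeric(1))
  means <- fvals[-1] - fvals[1]
  if (offset != 0 && !is.null(offset_agent)) {
    if (arms$agent[1] == offset_agent)
      means <- means - offset
    else
      means <- means + offset * (arms$agent[-1] == offset_agent)
  }
  mu <- stats::rnorm(1, truth$placebo_mean, truth$placebo_sd)
  delta <- if (truth$sigma > 0) rmultiarm_delta(means, truth$sigma)
           else means
  p <- stats::plogis(mu + c(0, delta))
  data.frame(study = names(layout)[i], agent = arms$agent,
             dose = arms$dose_std,
             responders = stats::rbinom(nrow(arms), truth$n_per_arm, p),
             sample_size = truth$n_per_arm, stringsAsFactors = FALSE)
}

#' Inject inconsistency into a simulated network
#'
#' Regenerates the outcomes of the studies that sit on one edge of a
#' loop — the two-arm head-to-head studies whose agents are exactly the
#' pair given — with a fixed log-odds offset added to the relative
#' effect of the second agent versus the first.  All other studies are
#' untouched (same sub-seeds, byte-identical rows), so the injected
#' disagreement between direct and indirect evidence is localized to the
#' chosen edge; multi-arm studies containing the pair sit on several
#' edges at once and are deliberately left alone.
#'
#' @param net a network produced by [simulate_network()].
#' @param edge character vector of two agent names; the two-arm direct
#'   studies of this comparison are regenerated.
#' @param offset log-odds offset added to the edge's direct relative
#'   effects.
#' @return the modified network; attribute `"truth"` gains an
#'   `inconsistency` record.
#' @export
inject_inconsistency <- function(net, edge, offset = 1.0) {
  tr <- attr(net, "truth")
  if (is.null(tr))
    stop("net must come from simulate_network() (truth record required)")
  stopifnot(length(edge) == 2)
  target <- which(vapply(tr$layout, function(a)
    setequal(a$agent, edge) && nrow(a) == 2, logical(1)))
  if (!length(target))
    stop("no two-arm study compares ", edge[1], " and ", edge[2])
  arms <- net$arms
  for (i in target) {
    regen <- simulate_study(tr$truth, tr$layout, i, tr$seed,
                            offset = offset, offset_agent = edge[2])
    rows <- which(arms$study == names(tr$layout)[i])
    ord <- match(paste(regen$agent, regen$dose),
                 paste(arms$agent[rows], arms$dose_std[rows]))
    arms$responders[rows[ord]] <- regen$responders
  }
  net$arms <- arms
  tr$inconsistency <- list(edge = edge, offset = offset,
                           studies = names(tr$layout)[target])
  attr(net, "truth") <- tr
  net
}

#' @export
print.network_truth <- function(x, ...) {
  cat("Simulated-network truth: ", x$n_studies, " studies, ",
      length(x$agents), " agents + ", x$reference, ", ",
      x$dose_model$name, " dose-response, sigma = ", x$sigma, "\n",
      sep = "")
  invisible(x)
}
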