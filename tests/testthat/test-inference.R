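test_that("the same seed and configuration reproduce the draws exactly", {
  net <- tiny_net()
  f1 <- fit_quick(net, model = "split", effect = "fixed", seed = 3)
  f2 <- fit_quick(net, model = "split", effect = "fixed", seed = 3)
  expect_identical(dosenma:::pooled_draws(f1$samples),
                   dosenma:::pooled_draws(f2$samples))
  f3 <- fit_quick(net, model = "split", effect = "fixed", seed = 4)
  expect_false(identical(dosenma:::pooled_draws(f1$samples),
                         dosenma:::pooled_draws(f3$samples)))
})

test_that("retained draws per chain equal sample / thin", {
  ctl <- mcmc_control(chains = 2, burnin = 500, sample = 1200, thin = 4,
                      seed = 1)
  fit <- suppressWarnings(mbnma(tiny_net(), model = "split",
                                effect = "fixed", control = ctl))
  expect_length(fit$samples, 2)
  expect_equal(nrow(fit$samples[[1]]), 1200 / 4)
  expect_error(mcmc_control(sample = 300, thin = 10), "100 retained")
})

test_that("fitted arm probabilities match a conjugate-style oracle", {
  # single two-arm study, fixed effect, vague priors: the posterior mean
  # of each arm probability is governed by its own binomial likelihood.
  # Oracle: numeric integration of the logit-normal-binomial posterior.
  arms <- data.frame(study = "s1", agent = c("placebo", "drug"),
                     dose = c(0, 1), responders = c(30, 55),
                     sample_size = c(100, 100))
  net <- dose_network(arms, standardized = TRUE)
  fit <- fit_quick(net, model = "split", effect = "fixed", seed = 2)
  post_mean <- function(r, n) {
    # deterministic grid quadrature; the integrand is a narrow peak
    mu <- seq(-8, 8, length.out = 40001)
    loglik <- r * stats::plogis(mu, log.p = TRUE) +
      (n - r) * stats::plogis(-mu, log.p = TRUE) +
      stats::dnorm(mu, 0, sqrt(1000), log = TRUE)
    w <- exp(loglik - max(loglik))
    sum(stats::plogis(mu) * w) / sum(w)
  }
  fitted_mean <- colMeans(fit$fitted)
  expect_equal(fitted_mean[[1]], post_mean(30, 100), tolerance = 0.02)
  expect_equal(fitted_mean[[1]], 30 / 100, tolerance = 0.02)
})

test_that("fixed-effect NMA recovers a known relative effect", {
  # 20 placebo-controlled studies of one agent at dose 1, true log-odds
  # ratio 0.7; the posterior median must land within 3 posterior SDs
  truth <- network_truth(agents = "drugA", dose_model = "linear",
                         params = list(slope = 0.7),
                         sigma = 0, n_studies = 20, doses = 1,
                         prop_three_arm = 0, prop_head_to_head = 0)
  net <- simulate_network(truth, seed = 8)
  fit <- fit_quick(net, model = "split", effect = "fixed", seed = 1)
  d <- dosenma:::pooled_draws(fit$samples)[, "d[2]"]
  expect_lt(abs(stats::median(d) - 0.7), 3 * stats::sd(d))
})

test_that("split-Rhat flags separated chains and passes identical ones", {
  # identical chains: zero between-chain information, exactly 1
  x <- cbind(stats::rnorm(500), 0)
  x[, 2] <- x[, 1]
  expect_identical(split_rhat(x), 1)
  # two chains offset by a large constant: far above the 1.05 threshold
  y <- cbind(stats::rnorm(500), stats::rnorm(500) + 50)
  expect_gt(split_rhat(y), 5)
  # constant chains at different values: infinite
  expect_identical(split_rhat(cbind(rep(1, 100), rep(2, 100))), Inf)
  # well-mixed independent draws: close to 1
  set.seed(2)
  z <- matrix(stats::rnorm(3000), ncol = 3)
  expect_lt(split_rhat(z), 1.05)
  expect_error(split_rhat(matrix(1:10, ncol = 1)), "2 chains")
})

test_that("summaries apply transforms draw-wise", {
  set.seed(5)
  # 2001 draws: the 2.5/50/97.5 percentiles are exact order statistics,
  # so the monotone-transform identity holds exactly
  draws <- matrix(stats::rnorm(4002), ncol = 2,
                  dimnames = list(NULL, c("led50[2]", "other")))
  tab <- dosenma:::summarize_draws(
    draws, list(ed50 = list(par = "led50", fun = exp)),
    probs = c(0.025, 0.975))
  raw <- tab[tab$parameter == "led50[2]", ]
  tr <- tab[tab$parameter == "ed50[2]", ]
  # monotone transform: quantiles of exp(draws) = exp(quantiles of draws)
  expect_equal(tr$median, exp(raw$median))
  expect_equal(tr$lower, exp(raw$lower))
  expect_equal(tr$upper, exp(raw$upper))
  # degenerate draws: log-ED50 identically 0 reports ED50 1 (1-1)
  d0 <- matrix(0, 100, 1, dimnames = list(NULL, "led50[2]"))
  t0 <- dosenma:::summarize_draws(
    d0, list(ed50 = list(par = "led50", fun = exp)), c(0.025, 0.975))
  expect_equal(unlist(t0[t0$parameter == "ed50[2]", c("median", "lower",
                                                      "upper")]),
               c(median = 1, lower = 1, upper = 1))
  # symmetric draws: median near 0
  expect_lt(abs(tab$median[tab$parameter == "other"]), 0.1)
  # interval ordering invariant
  expect_true(all(tab$lower <= tab$median & tab$median <= tab$upper))
})
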