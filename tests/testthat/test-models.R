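test_that("an s-node network has s - 1 basic parameters", {
  net <- small_sim_net(seed = 3)
  mod <- mbnma_model(net, model = "split", effect = "fixed")
  nt <- mod$data$nt
  expect_true(grepl("d[1] <- 0", mod$code, fixed = TRUE))
  expect_true(grepl("for (k in 2:nt)", mod$code, fixed = TRUE))
  # contrasts are differences of basic parameters (consistency equations)
  expect_true(grepl("d[t[i,k]] - d[t[i,1]]", mod$code, fixed = TRUE))
  fit <- fit_quick(net, model = "split", effect = "fixed")
  d_cols <- grep("^d\\[", colnames(dosenma:::pooled_draws(fit$samples)))
  expect_length(d_cols, nt)  # includes the structural zero d[1]
  expect_equal(unique(dosenma:::pooled_draws(fit$samples)[, "d[1]"]), 0)
})

test_that("UME frees one mean per observed contrast in a loop", {
  net <- loop_net()
  # loop P-A, P-B, A-B: 3 free UME means, but only 2 basic parameters
  ume <- mbnma_model(net, model = "ume", effect = "random")
  expect_equal(nrow(ume$pairs), 3)
  nma <- mbnma_model(net, model = "split", effect = "random")
  expect_equal(nma$data$nt - 1, 2)
})

test_that("UME means coincide with split-NMA basic parameters when no
           indirect evidence exists", {
  # only two-arm placebo-controlled trials: every contrast is direct-only
  net <- simulate_network(
    network_truth(n_studies = 12, prop_three_arm = 0,
                  prop_head_to_head = 0, doses = c(1, 2)), seed = 5)
  fs <- fit_quick(net, model = "split", effect = "random", seed = 2)
  fu <- fit_quick(net, model = "ume", effect = "random", seed = 3)
  trt <- fs$treatments$treatment
  for (j in seq_len(nrow(fu$pairs))) {
    stopifnot(fu$pairs$treatment1[j] == "placebo")
    k <- match(fu$pairs$treatment2[j], trt)
    med_nma <- fs$summary$median[fs$summary$parameter == sprintf("d[%d]", k)]
    med_ume <- fu$summary$median[fu$summary$parameter == sprintf("dd[%d]", j)]
    expect_equal(med_ume, med_nma, tolerance = 0.12)
  }
})

test_that("class effects are validated", {
  net <- small_sim_net(seed = 1)
  expect_error(mbnma_model(net, model = "split", class_effect = "ed50"),
               "only defined for dose-response")
  expect_error(mbnma_model(net, model = "emax", class_effect = "nope"),
               "unknown class-effect parameter")
  one_agent <- simulate_network(
    network_truth(agents = "drugA",
                  params = list(emax = 1.5, led50 = 0),
                  n_studies = 6, prop_three_arm = 0,
                  prop_head_to_head = 0), seed = 1)
  expect_error(mbnma_model(one_agent, model = "emax", class_effect = "ed50"),
               "at least 2 active agents")
})

test_that("exchangeable parameters appear as hierarchical draws", {
  net <- small_sim_net(seed = 1)
  mod <- mbnma_model(net, model = "emax", class_effect = c("emax", "ed50"))
  expect_true(grepl("emax[a] ~ dnorm(m_emax, tau_emax)", mod$code,
                    fixed = TRUE))
  expect_true(grepl("led50[a] ~ dnorm(m_led50, tau_led50)", mod$code,
                    fixed = TRUE))
  # wider prior on the Emax class SD than on the log-ED50 class SD
  expect_true(grepl("sd_emax ~ dunif(0, 20)", mod$code, fixed = TRUE))
  expect_true(grepl("sd_led50 ~ dunif(0, 4)", mod$code, fixed = TRUE))
})

test_that("a disconnected coded network cannot be fitted jointly", {
  arms <- data.frame(study = rep(c("s1", "s2"), each = 2),
                     agent = c("placebo", "A", "A", "B"),
                     dose = c(0, 1, 2, 1),
                     responders = 5, sample_size = 20)
  net <- dose_network(arms, standardized = TRUE)
  expect_error(mbnma_model(net, model = "split"), "disconnected")
  # the dose-response model bridges the doses: agent-level graph connects
  expect_s3_class(mbnma_model(net, model = "emax"), "mbnma_model")
})

test_that("the half-normal SD prior is accepted by the sampler", {
  fit <- fit_quick(tiny_net(), model = "linear", effect = "random",
                   priors = mbnma_priors(between_sd = prior_half_normal(100)))
  sd_med <- fit$summary$median[fit$summary$parameter == "sd"]
  expect_true(sd_med > 0 && sd_med < 1)
})

test_that("placebo model needs at least two placebo arms", {
  arms <- data.frame(study = c("s1", "s1", "s2", "s2"),
                     agent = c("placebo", "A", "A", "B"),
                     dose = c(0, 1, 1, 1), responders = 5, sample_size = 20)
  net <- dose_network(arms, standardized = TRUE)
  expect_error(placebo_model(net), "single")
  h2h_only <- dose_network(arms[3:4, ], standardized = TRUE)
  expect_error(placebo_model(h2h_only), "no placebo arms")
})

test_that("placebo model concentrates near logit(1/2) for balanced arms", {
  arms <- data.frame(study = rep(paste0("s", 1:6), each = 2),
                     agent = rep(c("placebo", "A"), 6),
                     dose = rep(c(0, 1), 6),
                     responders = rep(c(500, 600), 6),
                     sample_size = 1000)
  net <- dose_network(arms, standardized = TRUE)
  pf <- placebo_model(net, control = quick_ctl())
  m <- posterior_summary(pf$samples)
  expect_lt(abs(m$median[m$parameter == "m"]), 0.1)
})

test_that("placebo model recovers the generating mean across seeds", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    mu <- stats::rnorm(12, -1.5, 0.3)
    arms <- data.frame(study = rep(paste0("s", 1:12), each = 2),
                       agent = rep(c("placebo", "A"), 12),
                       dose = rep(c(0, 1), 12),
                       responders = c(rbind(stats::rbinom(12, 300,
                                                          stats::plogis(mu)),
                                            150)),
                       sample_size = 300)
    net <- dose_network(arms, standardized = TRUE)
    pf <- placebo_model(net, control = quick_ctl(seed = s))
    sm <- posterior_summary(pf$samples)
    row <- sm[sm$parameter == "m", ]
    hits <- hits + (row$lower <= -1.5 && -1.5 <= row$upper)
  }
  expect_gte(hits, 9)
})

test_that("relative effects are untouched by running the placebo model", {
  # separate models share no parameters: same seed, same draws either way
  net <- small_sim_net(seed = 6)
  f1 <- fit_quick(net, model = "split", effect = "fixed", seed = 4)
  invisible(placebo_model(net, control = quick_ctl(seed = 9)))
  f2 <- fit_quick(net, model = "split", effect = "fixed", seed = 4)
  expect_identical(dosenma:::pooled_draws(f1$samples),
                   dosenma:::pooled_draws(f2$samples))
})
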