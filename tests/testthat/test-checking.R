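test_that("binomial residual deviance has its closed forms", {
  # fitted = observed gives zero
  expect_equal(binomial_residual_deviance(5, 10, 0.5), 0)
  expect_equal(binomial_residual_deviance(3, 10, 0.3), 0)
  # boundary count with the 0 log 0 convention
  expect_equal(binomial_residual_deviance(0, 10, 0.5), 2 * 10 * log(2))
  expect_error(binomial_residual_deviance(5, 10, 1), "strictly in")
  expect_error(binomial_residual_deviance(5, 10, 0), "strictly in")
})

test_that("a single posterior draw gives pD = 0 and DIC = Dbar exactly", {
  rep1 <- plugin_dic(matrix(c(0.3, 0.6), 1), observed = c(3, 7),
                     family = "binomial", n = c(10, 10))
  expect_identical(rep1$pD, 0)
  expect_identical(rep1$DIC, rep1$Dbar)
})

test_that("per-point contributions are nonnegative and sum to Dbar", {
  fit <- fit_quick(small_sim_net(seed = 2), model = "split",
                   effect = "random")
  dev <- dic(fit)
  expect_true(all(dev$per_point$contribution >= 0))
  expect_equal(sum(dev$per_point$contribution), dev$Dbar)
  expect_equal(dev$n_datapoints, nrow(fit$arm_map))
  expect_equal(dev$pD + dev$D_plugin, dev$Dbar)
})

test_that("pD approximates the free parameter count in a normal toy", {
  # J studies, y_j ~ N(theta_j, se^2), flat-ish prior: the posterior is
  # theta_j | y ~ N(y_j, se^2) exactly, and pD should approach J
  set.seed(3)
  J <- 12; se <- rep(1, J)
  y <- stats::rnorm(J, 0, 2)
  theta_draws <- sapply(seq_len(J), function(j) stats::rnorm(4000, y[j], 1))
  rep <- plugin_dic(theta_draws, observed = y, family = "normal", se = se)
  expect_lt(abs(rep$pD - J) / J, 0.15)
})

test_that("deviance is invariant to arm ordering and study relabeling", {
  draws <- matrix(stats::runif(400, 0.2, 0.8), 50)
  r <- c(3, 5, 7, 2, 8, 4, 6, 1); n <- rep(10, 8)
  a <- plugin_dic(draws, r, "binomial", n = n)
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  b <- plugin_dic(draws[, perm], r[perm], "binomial", n = n[perm])
  expect_equal(b$Dbar, a$Dbar)
  expect_equal(b$pD, a$pD)
  expect_equal(b$per_point$contribution, a$per_point$contribution[perm])
})

test_that("model comparison flags DIC differences below three", {
  fake_fit <- function(dic_val, sd_med) {
    structure(list(
      model = "split", effect = "random", dose_model = NULL,
      data_sig = "same",
      deviance = structure(list(Dbar = dic_val - 40, pD = 40 - 20,
                                D_plugin = dic_val - 60, DIC = dic_val,
                                per_point = data.frame(), n_datapoints = 80),
                           class = "deviance_report"),
      summary = data.frame(parameter = "sd", label = "sd",
                           median = sd_med, lower = sd_med - 0.1,
                           upper = sd_med + 0.1)),
      class = "mbnma")
  }
  tab <- compare_fits(a = fake_fit(320, 0.3), b = fake_fit(325, 0.4))
  expect_equal(tab$model, c("a", "b"))  # sorted by DIC
  expect_null(attr(tab, "close_pairs"))  # 5 units apart: meaningful
  tab2 <- compare_fits(a = fake_fit(320, 0.3), b = fake_fit(322, 0.4))
  expect_equal(attr(tab2, "close_pairs")$dDIC, 2)
  expect_equal(names(tab)[1:4], c("model", "DIC", "pD", "resdev"))
  bad <- fake_fit(320, 0.3); bad$data_sig <- "other"
  expect_error(compare_fits(a = fake_fit(320, 0.3), b = bad),
               "same dataset")
})

test_that("identical fits compare with zero differences", {
  fit <- fit_quick(tiny_net(), model = "split", effect = "random")
  tab <- compare_fits(one = fit, two = fit)
  expect_equal(diff(tab$DIC), 0)
  expect_equal(attr(tab, "close_pairs")$dDIC, 0)
})

test_that("the inconsistency screen pairs points and checks data match", {
  net <- small_sim_net(seed = 3)
  fc <- fit_quick(net, model = "split", effect = "random", seed = 1)
  fu <- fit_quick(net, model = "ume", effect = "random", seed = 2)
  ic <- inconsistency_check(fc, fu)
  expect_equal(nrow(ic$per_point), nrow(net$arms))
  expect_equal(ic$per_point$difference,
               ic$per_point$dev_consistency - ic$per_point$dev_ume)
  expect_true(is.logical(ic$flag) && is.logical(ic$flag_median))
  other <- fit_quick(small_sim_net(seed = 4), model = "ume",
                     effect = "random")
  expect_error(inconsistency_check(fc, other), "same data")
  expect_error(inconsistency_check(fc, fc), "unrelated-mean-effects")
})

test_that("posterior-predictive check covers most self-simulated arms", {
  net <- small_sim_net(seed = 5)
  fit <- fit_quick(net, model = "emax", effect = "random")
  tab <- vpc(fit, nsim = 400, seed = 1)
  expect_equal(nrow(tab), nrow(net$arms))
  expect_true(all(tab$pred_lower <= tab$pred_median &
                    tab$pred_median <= tab$pred_upper))
  expect_gte(mean(tab$inside), 0.85)
})

test_that("replicate datasets from a fit keep the network layout", {
  fit <- fit_quick(tiny_net(), model = "linear", effect = "random")
  sims <- simulate(fit, nsim = 3, seed = 2)
  expect_length(sims, 3)
  expect_equal(sims[[1]]$study, fit$arm_map$study)
  expect_true(all(sims[[2]]$responders >= 0 &
                    sims[[2]]$responders <= sims[[2]]$sample_size))
  expect_false(identical(sims[[1]]$responders, sims[[2]]$responders))
})
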