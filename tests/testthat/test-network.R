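test_that("dose standardization divides by each agent's common dose", {
  net <- tiny_net()
  # 100 mg at a 50 mg common dose is 2 common-dose multiples
  expect_equal(net$arms$dose_std[net$arms$dose_raw == 100], 2.0)
  expect_equal(net$arms$dose_std[net$arms$dose_raw == 50], 1.0)
  expect_equal(net$arms$dose_std[net$arms$agent == "placebo"], c(0, 0))
  # invariant to the raw unit: rescale doses and common dose together
  arms2 <- data.frame(study = rep(c("s1", "s2"), each = 2),
                      agent = net$arms$agent,
                      dose = net$arms$dose_raw * 1000,
                      responders = net$arms$responders,
                      sample_size = net$arms$sample_size)
  net2 <- dose_network(arms2, common_doses = c(sumatriptan = 50000))
  expect_equal(net2$arms$dose_std, net$arms$dose_std)
})

test_that("arm-level validation rejects malformed input", {
  base <- data.frame(study = c("s1", "s1"), agent = c("placebo", "drug"),
                     dose = c(0, 10), responders = c(5, 5),
                     sample_size = c(20, 20))
  cd <- c(drug = 10)
  expect_error(dose_network(base[-2], cd), "missing column")
  bad <- base; bad$responders[2] <- 25
  expect_error(dose_network(bad, cd), "responders")
  bad <- base; bad$dose[2] <- -1
  expect_error(dose_network(bad, cd), "negative dose")
  expect_error(dose_network(base, c(other = 1)), "absent from common_doses")
  bad <- rbind(base, data.frame(study = "s2", agent = "drug", dose = 10,
                                responders = 3, sample_size = 10))
  expect_error(dose_network(bad, cd), "single-arm")
  bad <- rbind(base, base[2, ])
  expect_error(dose_network(bad, cd), "duplicate")
})

test_that("writing then reading reproduces the network field for field", {
  net <- tiny_net()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dose_network(net, path)
  back <- read_dose_network(path, common_doses = c(sumatriptan = 50))
  expect_equal(back$arms, net$arms)
  expect_equal(back$agents, net$agents)
  expect_equal(back$common_doses, net$common_doses)
})

test_that("edge table counts within-study comparisons", {
  # chain P-A, A-B: one comparison per edge, connected at agent level
  arms <- data.frame(
    study = rep(c("s1", "s2"), each = 2),
    agent = c("placebo", "A", "A", "B"),
    dose = c(0, 1, 2, 1),
    responders = 5, sample_size = 20)
  net <- dose_network(arms, standardized = TRUE)
  ag <- network_summary(net, level = "agent")
  expect_equal(nrow(ag), 2)
  expect_true(attr(ag, "connected"))
  expect_setequal(paste(ag$node1, ag$node2), c("placebo A", "A B"))
  expect_equal(ag$comparisons, c(1L, 1L))
  # same data at treatment level: A appears at two doses, no shared node
  tr <- network_summary(net, level = "treatment")
  expect_false(attr(tr, "connected"))
  expect_warning(split_doses(net), "disconnected")
})

test_that("a three-arm study increments all three of its edges once", {
  arms <- data.frame(study = "s1", agent = c("placebo", "A", "B"),
                     dose = c(0, 1, 1), responders = 5, sample_size = 20)
  net <- dose_network(arms, standardized = TRUE)
  es <- network_summary(net, level = "agent")
  expect_equal(nrow(es), 3)
  expect_equal(es$comparisons, rep(1L, 3))
})

test_that("total edge comparisons equal the sum of per-study arm pairs", {
  net <- small_sim_net(seed = 4)
  es <- network_summary(net, level = "treatment")
  arms_per_study <- table(net$arms$study)
  expect_equal(sum(es$comparisons), sum(choose(arms_per_study, 2)))
})

test_that("lumped coding collapses doses and flags multidose studies", {
  arms <- data.frame(
    study = c("s1", "s1", "s1", "s2", "s2"),
    agent = c("placebo", "A", "A", "placebo", "A"),
    dose = c(0, 1, 2, 0, 1),
    responders = 5, sample_size = 20)
  net <- dose_network(arms, standardized = TRUE)
  lumped <- lump_doses(net)
  expect_equal(nrow(treatments(lumped)), 2)  # placebo + A
  expect_equal(attr(lumped, "multidose_studies"), "s1")
  # the model layer codes both A arms as the same treatment: delta mean 0
  mod <- mbnma_model(lumped, model = "lumped", effect = "fixed")
  expect_equal(mod$data$t[1, 2], mod$data$t[1, 3])
  # single dose per agent: no flags
  expect_equal(length(attr(lump_doses(tiny_net()), "multidose_studies")), 0)
})

test_that("split coding gives one node per agent-dose pair", {
  net <- small_sim_net(seed = 2)
  trt <- treatments(net, level = "treatment")
  key <- unique(paste(net$arms$agent, net$arms$dose_std))
  expect_equal(nrow(trt), length(key))
  # placebo arms all map to the single reference node
  expect_equal(sum(trt$agent == "placebo"), 1)
  expect_equal(trt$treatment[1], "placebo")
})

test_that("arm 1 is placebo when present, else lowest treatment index", {
  net <- loop_net()
  first_arms <- net$arms[!duplicated(net$arms$study), ]
  expect_equal(first_arms$agent, c("placebo", "placebo", "A"))
})
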