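# Shared fixtures: all data are generated in code, no files.

quick_ctl <- function(seed = 1, ...) {
  mcmc_control(preset = "test", seed = seed, ...)
}

# hand-sized two-study placebo-controlled network
tiny_net <- function() {
  arms <- data.frame(
    study = rep(c("s1", "s2"), each = 2),
    agent = c("placebo", "sumatriptan", "placebo", "sumatriptan"),
    dose = c(0, 100, 0, 50),
    responders = c(10, 25, 8, 18),
    sample_size = c(50, 50, 40, 45))
  dose_network(arms, common_doses = c(sumatriptan = 50))
}

# triangle loop at agent level: P-A, P-B, A-B
loop_net <- function() {
  arms <- data.frame(
    study = rep(c("s1", "s2", "s3"), each = 2),
    agent = c("placebo", "A", "placebo", "B", "A", "B"),
    dose = c(0, 1, 0, 1, 1, 1),
    responders = c(10, 20, 12, 25, 15, 22),
    sample_size = 50)
  dose_network(arms, standardized = TRUE)
}

small_sim_net <- function(seed = 1, ...) {
  simulate_network(network_truth(n_studies = 15, ...), seed = seed)
}

fit_quick <- function(net, ..., seed = 1) {
  suppressWarnings(mbnma(net, ..., control = quick_ctl(seed)))
}

# brute-force multivariate-normal log density (independent oracle for the
# sequential multi-arm decomposition)
mvn_logdens <- function(x, mean, Sigma) {
  k <- length(x)
  L <- chol(Sigma)
  z <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * k * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

compound_sym <- function(p, sigma) {
  S <- matrix(sigma^2 / 2, p, p)
  diag(S) <- sigma^2
  S
}
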