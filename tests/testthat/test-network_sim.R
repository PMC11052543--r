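test_that("step_probabilities implements the per-step law and its complement", {
  zero <- amha_parameters(matrix(0, 3, 3))
  p0 <- step_probabilities("A", c(A = 0, M = 0, H = 0), zero)
  expect_equal(unname(p0), c(1, 0, 0))

  # alpha_AM = 0.04/yr, beta_AM^H = 0.01/yr, N_H = 2, dt = 1 -> P(A->M) = 0.06
  alpha <- matrix(0, 3, 3); alpha[1, 2] <- 0.04
  beta <- array(0, c(3, 3, 3)); beta[1, 2, 3] <- 0.01
  pr <- amha_parameters(alpha, beta, reference_period_years = 1)
  p <- step_probabilities("A", c(A = 0, M = 0, H = 2), pr, dt_years = 1)
  expect_equal(unname(p["M"]), 0.06)
  expect_equal(sum(p), 1)

  # complement property on random parameter draws
  set.seed(8)
  for (i in 1:20) {
    pr2 <- amha_parameters(matrix(runif(9, 0, 0.05), 3, 3),
                           array(runif(27, 0, 0.01), c(3, 3, 3)),
                           reference_period_years = 1)
    st <- sample(c("A", "M", "H"), 1)
    cnt <- setNames(sample(0:3, 3, replace = TRUE), c("A", "M", "H"))
    expect_equal(sum(step_probabilities(st, cnt, pr2)), 1, tolerance = 1e-12)
  }

  # probabilities above 1 are an error asking for a smaller step
  big <- amha_parameters(matrix(2, 3, 3), reference_period_years = 1)
  expect_error(step_probabilities("A", c(A = 0, M = 0, H = 0), big),
               "smaller dt")
})

test_that("simulate_amha conserves nodes, keeps zero-rate states frozen and is bit-reproducible", {
  syn <- small_scenario()
  g <- syn$network
  states <- setNames(syn$truth$trajectories[, 1],
                     rownames(syn$truth$trajectories))
  zero <- amha_parameters(matrix(0, 3, 3))
  cfg <- sim_config(zero, horizon_years = 5, replicates = 2, seed = 5)
  sim <- simulate_amha(g, states, cfg)
  expect_true(all(apply(sim$fractions, c(1, 3), sum) == 1))
  expect_equal(sim$fractions[6, , 1], sim$fractions[1, , 1])

  p <- default_true_params()
  cfg2 <- sim_config(p, horizon_years = 10, replicates = 3, seed = 99)
  s1 <- simulate_amha(g, states, cfg2)
  s2 <- simulate_amha(g, states, cfg2)
  expect_identical(s1$fractions, s2$fractions)
  expect_identical(s1$final_states, s2$final_states)
  # different seed gives different draws
  cfg3 <- sim_config(p, horizon_years = 10, replicates = 3, seed = 100)
  expect_false(identical(simulate_amha(g, states, cfg3)$fractions,
                         s1$fractions))
  # fractions always sum to one
  expect_true(all(abs(apply(s1$fractions, c(1, 3), sum) - 1) < 1e-12))
})

test_that("one-step frequencies on a 2-node graph match exact enumeration (small run)", {
  g <- social_network(data.frame(source = "u", target = "v"))
  states <- c(u = "A", v = "M")
  p <- default_true_params()
  cfg <- sim_config(p, horizon_years = 1, dt_years = 1, replicates = 4000,
                    seed = 2)
  sim <- simulate_amha(g, states, cfg)
  pu <- step_probabilities("A", c(A = 0, M = 1, H = 0), p, 1)
  pv <- step_probabilities("M", c(A = 1, M = 0, H = 0), p, 1)
  for (su in c("A", "M", "H")) for (sv in c("A", "M", "H")) {
    expected <- pu[su] * pv[sv]
    got <- mean(sim$final_states["u", ] == su & sim$final_states["v", ] == sv)
    se <- sqrt(expected * (1 - expected) / 4000)
    expect_lt(abs(got - expected), max(4 * se, 1e-3))
  }
})

test_that("an absorbing heavy state grows monotonically in the replicate mean", {
  syn <- small_scenario()
  states <- setNames(syn$truth$trajectories[, 1],
                     rownames(syn$truth$trajectories))
  alpha <- matrix(0, 3, 3)
  alpha[1, 3] <- 0.02; alpha[2, 3] <- 0.05    # only flows into H
  p <- amha_parameters(alpha, reference_period_years = 1)
  cfg <- sim_config(p, horizon_years = 20, replicates = 10, seed = 3)
  sim <- simulate_amha(syn$network, states, cfg)
  expect_true(all(diff(sim$mean[, "H"]) >= 0))
})

test_that("asynchronous updating runs and conserves fractions", {
  syn <- small_scenario()
  states <- setNames(syn$truth$trajectories[, 1],
                     rownames(syn$truth$trajectories))
  cfg <- sim_config(default_true_params(), horizon_years = 4, replicates = 2,
                    seed = 11, scheme = "asynchronous")
  sim <- simulate_amha(syn$network, states, cfg)
  expect_true(all(abs(apply(sim$fractions, c(1, 3), sum) - 1) < 1e-12))
})

test_that("simulate_amha validates inputs and the dt guard", {
  g <- social_network(data.frame(source = "u", target = "v"))
  p <- default_true_params()
  expect_error(simulate_amha(g, c(u = "A"), sim_config(p)), "initial state")
  expect_error(simulate_amha(g, c(u = "A", v = "X"), sim_config(p)),
               "unknown state")
  big <- amha_parameters(matrix(0.9, 3, 3), reference_period_years = 1)
  expect_error(simulate_amha(g, c(u = "A", v = "M"),
                             sim_config(big, dt_years = 1)), "smaller dt")
})

test_that("forecast at horizon 0 reproduces the wave's observed fractions", {
  syn <- small_scenario()
  p <- default_true_params()
  fc <- forecast_amha(syn$panel, syn$network, p, wave = 2, horizon_years = 0,
                      replicates = 2, seed = 1)
  obs <- table(factor(syn$truth$trajectories[, 2], c("A", "M", "H")))
  expect_equal(unname(fc$sim$mean[1, ]), as.numeric(obs / sum(obs)))
  expect_equal(fc$n_dropped, 0)
})

test_that("forecast under the generator's own parameters tracks later waves", {
  syn <- small_scenario()
  truth <- syn$truth$params
  fc <- forecast_amha(syn$panel, syn$network, truth, wave = 1,
                      horizon_years = 16, dt_years = 4, replicates = 30,
                      seed = 77)
  cmp <- fc$comparison
  expect_equal(nrow(cmp), 4)
  # observed fractions fall within (slightly padded) replicate band
  ti <- vapply(cmp$year, function(y) which.min(abs(fc$calendar_years - y)),
               integer(1))
  for (i in seq_len(nrow(cmp))) {
    for (s in c("A", "M", "H")) {
      lo <- fc$sim$ci_lo[ti[i], s]; hi <- fc$sim$ci_hi[ti[i], s]
      pad <- 0.04
      expect_gt(cmp[i, paste0("obs_", s)], lo - pad)
      expect_lt(cmp[i, paste0("obs_", s)], hi + pad)
    }
  }
})

test_that("halving dt leaves 30-year means within the replicate band", {
  syn <- small_scenario()
  states <- setNames(syn$truth$trajectories[, 1],
                     rownames(syn$truth$trajectories))
  p <- default_true_params()
  run <- function(dt) simulate_amha(
    syn$network, states,
    sim_config(p, horizon_years = 30, dt_years = dt, replicates = 16,
               seed = 21))
  s1 <- run(1); s2 <- run(0.5)
  last1 <- dim(s1$fractions)[1]; last2 <- dim(s2$fractions)[1]
  for (s in c("A", "M", "H")) {
    width <- s1$ci_hi[last1, s] - s1$ci_lo[last1, s]
    expect_lt(abs(s1$mean[last1, s] - s2$mean[last2, s]), width)
  }
})
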