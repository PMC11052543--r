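test_that("aggregate_by_neighbor_count computes per-k fractions and at-risk weights", {
  tr <- make_transitions(from = rep("A", 10), to = c(rep("M", 2), rep("A", 8)),
                         n_M = 0)
  pts <- aggregate_by_neighbor_count(tr, "A", "M", "M")
  expect_equal(pts, data.frame(k = 0, fraction = 0.2, n = 10,
                               n_transitions = 2))
  # k values with no at-risk produce no point
  tr2 <- make_transitions(from = c("A", "A"), to = c("M", "A"), n_M = c(0, 2))
  pts2 <- aggregate_by_neighbor_count(tr2, "A", "M", "M")
  expect_equal(pts2$k, c(0, 2))
  expect_equal(nrow(aggregate_by_neighbor_count(tr2, "H", "A", "A")), 0)
})

test_that("fit_wls recovers exact lines and the frozen closed-form example", {
  pts <- data.frame(k = 0:2, fraction = c(0.1, 0.3, 0.5), n = c(100, 100, 100),
                    n_transitions = c(10, 30, 50))
  fit <- suppressWarnings(fit_wls(pts))   # exact fit: summary.lm warns
  expect_equal(fit$intercept, 0.1, tolerance = 1e-12)
  expect_equal(fit$slope, 0.2, tolerance = 1e-12)

  # equal weights reduce exactly to OLS (closed-form oracle)
  set.seed(3)
  for (rep in 1:5) {
    x <- 0:6
    y <- runif(7)
    ab <- ols_closed_form(x, y)
    fit <- fit_wls(data.frame(k = x, fraction = y, n = 50,
                              n_transitions = round(50 * y)))
    expect_equal(c(fit$intercept, fit$slope), unname(ab), tolerance = 1e-10)
  }

  # single k: intercept only
  one <- fit_wls(data.frame(k = 1, fraction = 0.25, n = 40,
                            n_transitions = 10))
  expect_equal(one$intercept, 0.25)
  expect_true(is.na(one$slope))
  expect_error(fit_wls(data.frame(k = numeric(), fraction = numeric(),
                                  n = numeric())), "no aggregated")
})

test_that("aggregated fractions track the generative law within binomial bounds", {
  # direct Bernoulli oracle: alpha = 0.05, beta = 0.03 per neighbour
  set.seed(17)
  alpha <- 0.05; beta <- 0.03
  k <- sample(0:4, 20000, replace = TRUE)
  hit <- rbinom(20000, 1, alpha + beta * k)
  tr <- make_transitions(from = rep("A", 20000),
                         to = ifelse(hit == 1, "M", "A"), n_M = k)
  pts <- aggregate_by_neighbor_count(tr, "A", "M", "M")
  for (i in seq_len(nrow(pts))) {
    p <- alpha + beta * pts$k[i]
    se <- sqrt(p * (1 - p) / pts$n[i])
    expect_lt(abs(pts$fraction[i] - p), 3.5 * se)
  }
  fit <- fit_wls(pts)
  expect_lt(abs(fit$intercept - alpha), 3 * fit$se_intercept)
  expect_lt(abs(fit$slope - beta), 3 * fit$se_slope)
})

test_that("logistic and linear fits agree at low rates and diverge under saturation", {
  # all k = 0: both collapse to the base rate
  tr0 <- make_transitions(from = rep("M", 200),
                          to = c(rep("H", 30), rep("M", 170)), n_H = 0)
  chk0 <- fit_logistic_check(tr0, "M", "H", "H")
  expect_equal(chk0$linear, chk0$logistic, tolerance = 1e-12)
  expect_equal(chk0$linear[1], 0.15)

  # saturating data: generated from a steep logistic curve
  set.seed(31)
  k <- rep(0:6, each = 2000)
  p <- plogis(-2 + 1.1 * k)
  hit <- rbinom(length(k), 1, p)
  trs <- make_transitions(from = rep("M", length(k)),
                          to = ifelse(hit == 1, "H", "M"), n_H = k)
  chk <- fit_logistic_check(trs, "M", "H", "H")
  expect_true(chk$nonlinear)
  expect_gt(chk$max_divergence, 0.02)
})

test_that("calibrate handles intercept-only data and missing origin states", {
  set.seed(7)
  frm <- rep(c("A", "M", "H"), each = 400)
  # spontaneous-only law with all neighbour counts zero
  params <- default_true_params()
  too <- vapply(frm, function(x) {
    pr <- params$alpha[x, ]; pr[is.na(pr)] <- 0
    pr[x] <- 1 - sum(pr, na.rm = TRUE)
    sample(c("A", "M", "H"), 1, prob = pr)
  }, character(1))
  tr <- make_transitions(frm, too)
  fit <- calibrate(tr, reference_period_years = 4)
  expect_equal(fit$beta, array(0, c(3, 3, 3)), ignore_attr = TRUE)
  agg <- aggregate_by_neighbor_count(tr, "A", "M", "M")
  expect_equal(fit$alpha["A", "M"], agg$fraction[1])

  expect_error(calibrate(make_transitions("A", "M")), "origin state")
})

test_that("calibrate recovers known rates on a synthetic scenario", {
  syn <- synth_scenario(scenario_config(n_persons = 4000, n_waves = 6,
                                        seed = 101))
  fit <- calibrate(syn$truth$transitions, reference_period_years = 4)
  truth <- syn$truth$params
  for (from in c("A", "M", "H")) for (to in c("A", "M", "H")) {
    if (from == to) next
    expect_lt(abs(fit$alpha[from, to] - truth$alpha[from, to]),
              3.3 * fit$se$alpha[from, to])
    b <- truth$beta[from, to, to]
    if (b > 0)
      expect_lt(abs(fit$beta[from, to, to] - b), 3.3 * fit$se$beta[from, to, to])
  }
  expect_true(all(fit$alpha >= 0, na.rm = TRUE))
  expect_true(all(fit$beta >= 0))
})

test_that("per-wave trend detects drift and rejects too-few waves", {
  build <- function(alphas, offset = 0) {
    do.call(rbind, lapply(seq_along(alphas), function(w) {
      set.seed(offset * 10 + w)
      n <- 3000
      k <- sample(0:3, n, replace = TRUE)      # no social effect: beta = 0
      hit <- rbinom(n, 1, alphas[w])
      make_transitions(rep("M", n), ifelse(hit == 1, "H", "M"), n_H = k,
                       wave = w)
    }))
  }
  trend_p <- function(tr) {
    class(tr) <- c("amha_transitions", "data.frame")
    t <- attr(per_wave_trend(tr, "alpha"), "trend")
    t[t$transition == "M->H", ]
  }
  # time-homogeneous data: the trend is a null test, so individual
  # replicates may reach p < 0.05 about 5% of the time; require the
  # non-significant fraction over 10 replicates to dominate
  null_ps <- vapply(1:10, function(i)
    trend_p(build(rep(0.08, 4), offset = i))$p_value, numeric(1))
  expect_gte(mean(null_ps > 0.05), 0.8)

  # alpha quadrupling across waves: always detected
  drift_rows <- lapply(1:5, function(i)
    trend_p(build(c(0.05, 0.10, 0.15, 0.20), offset = i)))
  expect_true(all(vapply(drift_rows, function(r) r$p_value < 0.05,
                         logical(1))))
  expect_true(all(vapply(drift_rows, function(r) r$slope > 0, logical(1))))

  single <- build(0.08)
  class(single) <- c("amha_transitions", "data.frame")
  expect_error(per_wave_trend(single), "three wave pairs")
})
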