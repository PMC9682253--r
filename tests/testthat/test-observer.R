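test_that("impulse-response density is a causal Gamma in the lag", {
  p <- observer_params(n_shape = 2, tau_I = 0.1)
  # mode of the lag distribution at (n - 1) tau_I = 100 ms
  m <- optimize(function(x) impulse_density(x, 0, p), c(0, 1),
                maximum = TRUE, tol = 1e-9)
  expect_equal(m$maximum, 0.1, tolerance = 1e-5)
  # causality: zero density before the beat
  expect_identical(impulse_density(c(-1, -1e-9), 0.0, p), c(0, 0))
  # exponential special case at the origin
  p1 <- observer_params(n_shape = 1, tau_I = 0.075)
  expect_equal(impulse_density(0, 0, p1), 1 / 0.075, tolerance = 1e-12)
})

test_that("impulse-response density integrates to one across shapes", {
  for (n in c(1, 1.5, 2, 5)) for (tau in c(0.01, 0.075, 0.1, 0.5)) {
    p <- observer_params(n_shape = n, tau_I = tau)
    z <- integrate(function(s) impulse_density(s, 0, p), 0, Inf,
                   rel.tol = 1e-9)$value
    expect_equal(z, 1, tolerance = 1e-6)
  }
})

test_that("spike trains are causal, reproducible and correctly scaled", {
  p <- observer_params(n_shape = 2, tau_I = 0.1)
  pattern <- generate_beat_times(6, 0.3, 0.05)
  set.seed(10)
  s1 <- sample_spike_train(pattern, p)
  expect_true(all(s1 >= pattern$times))
  set.seed(10)
  expect_identical(unclass(sample_spike_train(pattern, p)), unclass(s1))
  # mean lag over many draws matches n * tau_I
  set.seed(11)
  draws <- replicate(2e4, sample_spike_train(pattern, p) - pattern$times)
  se <- sqrt(2) * 0.1 / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.2), 3 * se)
})

test_that("interval prior has lognormal mode, mass and mean", {
  p <- observer_params(tau_Delta = 1.4, sigma = 1)
  m <- optimize(function(d) prior_density(d, p), c(0.01, 5),
                maximum = TRUE)
  expect_equal(m$maximum, 1.4 * exp(-1), tolerance = 1e-4)
  expect_equal(integrate(function(d) prior_density(d, p), 0, Inf,
                         rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
  # near-degenerate shape concentrates the mode at tau_Delta
  p0 <- observer_params(tau_Delta = 1.4, sigma = 0.02)
  m0 <- optimize(function(d) prior_density(d, p0), c(1, 2),
                 maximum = TRUE)
  expect_equal(m0$maximum, 1.4, tolerance = 1e-3)
  expect_error(prior_density(-0.1, p), "positive")
})

test_that("prior mean matches its closed form and quadrature", {
  expect_equal(round(prior_mean(observer_params(tau_Delta = 1.4,
                                                sigma = 1.1)), 1), 2.6)
  expect_equal(prior_mean(observer_params(tau_Delta = 2, sigma = 1)),
               2 * exp(0.5), tolerance = 1e-12)
  p <- observer_params(tau_Delta = 1.4, sigma = 1.1)
  quad <- integrate(function(d) d * prior_density(d, p), 0, Inf,
                    rel.tol = 1e-10)$value
  expect_equal(prior_mean(p), quad, tolerance = 1e-4)
  p0 <- observer_params(tau_Delta = 1.7, sigma = 0.01)
  expect_equal(prior_mean(p0), 1.7, tolerance = 1e-4)
})

test_that("pointwise losses evaluate their defining formulas", {
  p <- observer_params(tau_E = 0, tau_S = 0.1)
  expect_equal(loss_value("quadratic", 1.3, 1.3, p), 0)
  expect_equal(loss_value("margin", 0.1, 0.1, p), 0)
  pE <- observer_params(tau_E = 0.015)
  expect_equal(loss_value("absolute", 1.0, 1.015, pE), 0)
  expect_equal(loss_value("quadratic", 2, 2.5, p), 0.25)
  expect_error(loss_value("dirac", 1, 1, p), "Dirac")
})

test_that("noiseless spikes are inverted exactly by the estimator", {
  # constant-lag spikes: interval recovered exactly; first beat shifted
  # by the lag minus the likelihood's optimal lag (n - 1) tau_I
  p <- observer_params(n_shape = 2, tau_I = 0.1, prior_enabled = FALSE)
  spikes <- c(0.25, 0.55, 0.85, 1.15) # t1 = 0, delta = 0.3, lag 0.25
  est <- estimate_first_beat_and_interval(spikes, p, delta_ref = 0.3)
  expect_equal(est$delta_est, 0.3, tolerance = 1e-4)
  expect_equal(est$t1_est, 0.25 - 0.1, tolerance = 1e-4)
})

test_that("the prior pulls short intervals upward", {
  spikes <- c(0.21, 0.41, 0.61, 0.81) # delta = 0.2, well below prior mode
  p_off <- observer_params(n_shape = 2, tau_I = 0.05,
                           prior_enabled = FALSE)
  p_on <- observer_params(n_shape = 2, tau_I = 0.05, tau_Delta = 2,
                          sigma = 1)
  e_off <- estimate_first_beat_and_interval(spikes, p_off,
                                            delta_ref = 0.2)
  e_on <- estimate_first_beat_and_interval(spikes, p_on, delta_ref = 0.2)
  expect_gte(e_on$delta_est, e_off$delta_est - 1e-9)
})

test_that("exponential likelihood puts the first-beat time on the causal boundary", {
  p <- observer_params(n_shape = 1, tau_I = 0.075, prior_enabled = FALSE)
  set.seed(3)
  for (i in 1:10) {
    pattern <- generate_beat_times(4, 0.3, 0)
    spikes <- as.numeric(sample_spike_train(pattern, p))[1:3]
    est <- estimate_first_beat_and_interval(spikes, p, delta_ref = 0.3)
    bound <- min(spikes - (0:2) * est$delta_est)
    expect_equal(est$t1_est, bound, tolerance = 1e-10)
  }
})

test_that("MAP estimation agrees with a brute-force grid oracle", {
  set.seed(42)
  res <- 1e-4
  for (i in 1:50) {
    inst <- random_instance()
    est <- estimate_first_beat_and_interval(inst$spikes, inst$params,
                                            delta_ref = inst$delta)
    orc <- oracle_estimate_grid(inst$spikes, inst$params,
                                delta_lo = inst$delta / 3,
                                delta_hi = 3 * inst$delta, res = res)
    expect_lt(abs(est$delta_est - orc$delta), 2 * res)
    # the first-beat coordinate couples to the interval through the
    # (i - 1) * delta offsets, so its grid-step allowance carries the
    # interval discrepancy amplified by the spike count
    slack <- (length(inst$spikes) - 1) * abs(est$delta_est - orc$delta)
    expect_lt(abs(est$t1_est - orc$t1), 2 * res + slack)
    # the refined optimum is never worse than the oracle grid's best
    expect_gte(est$log_posterior,
               orc$lp - 1e-6 * max(1, abs(orc$lp)))
  }
})

test_that("closed-form predictions match numeric expected-loss optimization", {
  for (loss in c("dirac", "quadratic", "absolute")) {
    for (n in c(1, 2, 3.5)) {
      p <- observer_params(n_shape = n, tau_I = 0.075, tau_E = 0.015,
                           loss_kind = loss)
      cf <- predict_last_spike(0.1, 0.3, 4, p)
      nm <- predict_last_spike(0.1, 0.3, 4, p, method = "numeric")
      expect_equal(cf, nm, tolerance = 1e-4)
    }
  }
  # margin loss: bounded-window rule agrees with numeric minimization
  pm <- observer_params(n_shape = 2, tau_I = 0.1, tau_E = 0.01,
                        loss_kind = "margin")
  expect_equal(predict_last_spike(0.1, 0.3, 4, pm),
               predict_last_spike(0.1, 0.3, 4, pm, method = "numeric"),
               tolerance = 1e-4)
})

test_that("prediction shifts follow the loss geometry", {
  # quadratic: mean lag n tau_I; absolute: median lag; dirac: modal lag
  t_last <- 0.1 + 3 * 0.3
  p2 <- observer_params(n_shape = 1, tau_I = 0.075, tau_E = 0.015,
                        loss_kind = "quadratic")
  expect_equal(predict_last_spike(0.1, 0.3, 4, p2), t_last + 0.06,
               tolerance = 1e-12)
  p1 <- observer_params(n_shape = 1, tau_I = 0.075, tau_E = 0.015,
                        loss_kind = "absolute")
  expect_equal(predict_last_spike(0.1, 0.3, 4, p1),
               t_last + 0.075 * log(2) - 0.015, tolerance = 1e-12)
  pd <- observer_params(n_shape = 1, tau_I = 0.075, tau_E = 0,
                        loss_kind = "dirac")
  expect_equal(predict_last_spike(0.1, 0.3, 4, pd), t_last,
               tolerance = 1e-12)
})

test_that("a larger early shift strictly lowers every prediction", {
  for (loss in c("margin", "dirac", "quadratic", "absolute")) {
    preds <- vapply(c(0, 0.01, 0.03, 0.08), function(tE) {
      p <- observer_params(n_shape = 2, tau_I = 0.1, tau_E = tE,
                           loss_kind = loss)
      predict_last_spike(0.1, 0.3, 4, p)
    }, numeric(1L))
    expect_true(all(diff(preds) < 0))
  }
})

test_that("decisions compare predicted and actual spikes, ties are coin flips", {
  expect_identical(decide(1.0, 1.1), "late")
  expect_identical(decide(1.2, 1.1), "early")
  set.seed(99)
  ties <- replicate(1000, decide(1, 1))
  expect_true(all(ties %in% c("early", "late")))
  p_early <- mean(ties == "early")
  expect_lt(abs(p_early - 0.5), 3 * sqrt(0.25 / 1000))
  # determinism under a fixed seed
  set.seed(7); a <- replicate(20, decide(1, 1))
  set.seed(7); b <- replicate(20, decide(1, 1))
  expect_identical(a, b)
})
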