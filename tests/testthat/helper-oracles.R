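# Independent oracles used to cross-check the package's estimators and
# statistics. These deliberately avoid the package's own code paths.

# Log posterior of (t1, delta) for one spike vector, by direct density
# evaluation (dgamma / dlnorm), -Inf outside the causal region.
oracle_logpost <- function(t1, delta, spikes, params) {
  m <- length(spikes)
  lags <- spikes - (t1 + (seq_len(m) - 1) * delta)
  if (any(lags < 0)) return(-Inf)
  ll <- sum(dgamma(lags, shape = params$n_shape, scale = params$tau_I,
                   log = TRUE))
  if (params$prior_enabled)
    ll <- ll + dlnorm(delta, meanlog = log(params$tau_Delta),
                      sdlog = params$sigma, log = TRUE)
  ll
}

# Brute-force 2-D grid maximization of the posterior: a coarse pass over
# the given delta window followed by a fine pass at `res` resolution
# around the coarse optimum.
oracle_estimate_grid <- function(spikes, params, delta_lo, delta_hi,
                                 res = 1e-4) {
  m <- length(spikes)
  eval_delta <- function(deltas, t_step) {
    best <- list(lp = -Inf)
    for (d in deltas) {
      t_max <- min(spikes - (seq_len(m) - 1) * d)
      t_lo <- t_max - 6 * params$n_shape * params$tau_I
      ts <- seq(t_lo, t_max, by = t_step)
      lps <- vapply(ts, oracle_logpost, numeric(1L), delta = d,
                    spikes = spikes, params = params)
      i <- which.max(lps)
      if (lps[i] > best$lp)
        best <- list(lp = lps[i], t1 = ts[i], delta = d)
    }
    best
  }
  coarse_step <- 20 * res
  b <- eval_delta(seq(delta_lo, delta_hi, by = coarse_step), coarse_step)
  fine <- eval_delta(seq(max(delta_lo, b$delta - 2 * coarse_step),
                         min(delta_hi, b$delta + 2 * coarse_step),
                         by = res), res)
  fine
}

# Exact two-sided binomial p-value by full enumeration with the
# minimum-likelihood rule.
oracle_binom_p <- function(k, n, p0) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Kendall tau-b by direct concordant/discordant counting over all pairs.
oracle_kendall_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Random small estimation instance shared by the oracle-agreement tests.
random_instance <- function() {
  n_beats <- sample(3:5, 1L)
  delta <- runif(1L, 0.3, 0.6)
  params <- observer_params(
    tau_I = runif(1L, 0.03, 0.08),
    n_shape = sample(c(1, 1.5, 2, 3), 1L),
    tau_Delta = runif(1L, 0.8, 2),
    sigma = runif(1L, 0.7, 1.3),
    prior_enabled = sample(c(TRUE, FALSE), 1L))
  pattern <- generate_beat_times(n_beats, delta, 0)
  spikes <- as.numeric(sample_spike_train(pattern, params))
  list(spikes = spikes[-n_beats], delta = delta, params = params)
}
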