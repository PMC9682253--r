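#' Impulse-response density of the beat-to-spike lag
#'
#' The internal spike elicited by a beat at time `t` occurs at `s >= t`
#' with a Gamma density in the lag `s - t`: shape `n_shape` (asymmetry;
#' `n_shape = 1` is exponential, larger values are more symmetric) and
#' scale `tau_I`. The density is exactly zero for `s < t` (causality) and
#' its mode sits at lag `(n_shape - 1) * tau_I`.
#'
#' @param s Spike time(s) in seconds (vectorized).
#' @param t Beat time in seconds.
#' @param params An [observer_params()] object.
#' @return Density value(s) in 1/seconds.
#' @examples
#' p <- observer_params(n_shape = 2, tau_I = 0.1)
#' optimize(function(x) impulse_density(x, 0, p), c(0, 1),
#'          maximum = TRUE)$maximum # ~0.1 s
#' @export
impulse_density <- function(s, t, params) {
  validate_observer_params(params)
  dgamma(s - t, shape = params$n_shape, scale = params$tau_I)
}

#' Sample a spike train from a beat pattern
#'
#' Draws one internal spike per beat, `s_i = t_i + lag_i` with
#' independent Gamma(`n_shape`, `tau_I`) lags. Reproducible via
#' `set.seed()`.
#'
#' @param pattern A [generate_beat_times()] pattern.
#' @param params An [observer_params()] object.
#' @return An object of class `spike_train`: numeric vector of spike
#'   times, one per beat, each `>= ` its beat time.
#' @export
sample_spike_train <- function(pattern, params) {
  stopifnot(inherits(pattern, "beat_pattern"))
  validate_observer_params(params)
  lags <- rgamma(pattern$n_beats, shape = params$n_shape,
                 scale = params$tau_I)
  structure(pattern$times + lags, class = "spike_train")
}

#' Prior density over the estimated inter-beat interval
#'
#' Lognormal belief about plausible inter-beat intervals: the scaled
#' interval `delta_e / tau_Delta` follows a standard lognormal with
#' shape `sigma`. The mode is at `tau_Delta * exp(-sigma^2)` (about
#' `tau_Delta / 3` when `sigma = 1`) and the mean at
#' `tau_Delta * exp(sigma^2 / 2)`.
#'
#' @param delta_e Candidate interval(s) in seconds (> 0).
#' @param params An [observer_params()] object.
#' @param log If `TRUE`, return the log density.
#' @return Density in 1/seconds.
#' @export
prior_density <- function(delta_e, params, log = FALSE) {
  validate_observer_params(params)
  if (any(!is.finite(delta_e)) || any(delta_e <= 0))
    stop("'delta_e' must be positive and finite", call. = FALSE)
  dlnorm(delta_e, meanlog = base::log(params$tau_Delta),
         sdlog = params$sigma, log = log)
}

#' Mean of the interval prior
#'
#' Closed form `tau_Delta * exp(sigma^2 / 2)`.
#'
#' @param params An [observer_params()] object.
#' @return Prior mean in seconds.
#' @examples
#' prior_mean(observer_params(tau_Delta = 1.4, sigma = 1.1)) # ~2.6 s
#' @export
prior_mean <- function(params) {
  validate_observer_params(params)
  params$tau_Delta * exp(params$sigma^2 / 2)
}

#' Pointwise loss between a predicted and a realized spike time
#'
#' Evaluates the cost of predicting `s_star` when the last spike lands at
#' `s_prime`, after the better-early-than-late shift `tau_E` is applied
#' to the prediction:
#' margin `1 - ((s_star + tau_E)/tau_S) * (s_prime/tau_S)`,
#' quadratic `((s_star + tau_E) - s_prime)^2`, and
#' absolute `|(s_star + tau_E) - s_prime|`.
#' The Dirac loss has no pointwise value (it is a distribution, not a
#' function) and is handled analytically inside [predict_last_spike()];
#' requesting it here is an error.
#'
#' @param loss_kind One of `"margin"`, `"quadratic"`, `"absolute"`.
#' @param s_star Predicted time in seconds (vectorized).
#' @param s_prime Realized time in seconds (vectorized).
#' @param params An [observer_params()] object (supplies `tau_E`, `tau_S`).
#' @return Dimensionless loss value(s).
#' @export
loss_value <- function(loss_kind, s_star, s_prime, params) {
  validate_observer_params(params)
  shifted <- s_star + params$tau_E
  switch(loss_kind,
    margin = 1 - (shifted / params$tau_S) * (s_prime / params$tau_S),
    quadratic = (shifted - s_prime)^2,
    absolute = abs(shifted - s_prime),
    dirac = stop("the Dirac loss cannot be evaluated pointwise; ",
                 "it is resolved analytically in predict_last_spike()",
                 call. = FALSE),
    stop("unknown 'loss_kind': ", loss_kind, call. = FALSE))
}

# Default profile-search settings for the interval estimate. The search
# spans [delta_ref/4, 4 * max(prior mean, delta_ref)] on a log grid with
# three zoom stages; the final grid step is ~6e-5 relative.
estimation_grid <- function(params, delta_ref, n_coarse = 64L,
                            n_zoom = 24L, n_stages = 3L) {
  upper_ref <- if (params$prior_enabled)
    max(prior_mean(params), delta_ref) else delta_ref
  list(lo = delta_ref / 4, hi = 4 * upper_ref,
       n_coarse = as.integer(n_coarse), n_zoom = as.integer(n_zoom),
       n_stages = as.integer(n_stages))
}

# Batch MAP estimation: spikes is an n_trials x m matrix of the first
# m = N - 1 spike times. Returns a data frame.
estimate_map_batch <- function(spikes, params, grid) {
  res <- .estimate_map_cpp(spikes, params$tau_I, params$n_shape,
                           params$tau_Delta, params$sigma,
                           params$prior_enabled,
                           grid$lo, grid$hi, grid$n_coarse, grid$n_zoom,
                           grid$n_stages)
  as.data.frame(res)
}

#' Estimate the first-beat time and inter-beat interval from spikes
#'
#' Stage one of the observer: maximum-a-posteriori estimation of
#' `(t1, Delta)` from the spikes of the first N - 1 beats, maximizing the
#' product of the interval prior (if enabled) and the Gamma
#' impulse-response likelihood of each spike, subject to causality
#' (`t1 + (i-1) Delta <= s_i` for every spike). The interval is profiled
#' on a log-spaced grid with zoom refinement; for each candidate interval
#' the first-beat time is solved exactly (boundary optimum for
#' `n_shape = 1`, Newton on the concave profile likelihood otherwise).
#'
#' @param spikes Numeric vector of spike times for one trial (at least
#'   two), or an `n_trials x m` matrix for batch estimation.
#' @param params An [observer_params()] object.
#' @param delta_ref Reference interval centering the search range;
#'   defaults to the mean spacing of the spikes.
#' @param grid Optional search settings from `estimation_grid()`.
#' @return For vector input, a list of class `estimation_result` with
#'   `t1_est`, `delta_est`, `log_posterior`; for matrix input, a data
#'   frame with those columns, one row per trial.
#' @examples
#' p <- observer_params(n_shape = 2, tau_I = 0.1, prior_enabled = FALSE)
#' # noiseless spikes at a constant lag: interval recovered exactly,
#' # first beat shifted by lag minus the impulse-response mode
#' est <- estimate_first_beat_and_interval(c(0.2, 0.5, 0.8), p,
#'                                         delta_ref = 0.3)
#' est$delta_est
#' @export
estimate_first_beat_and_interval <- function(spikes, params,
                                             delta_ref = NULL,
                                             grid = NULL) {
  validate_observer_params(params)
  vec_in <- !is.matrix(spikes)
  if (vec_in) spikes <- matrix(as.numeric(spikes), nrow = 1L)
  if (ncol(spikes) < 2)
    stop("at least two spikes are needed to estimate an interval",
         call. = FALSE)
  if (any(!is.finite(spikes)))
    stop("spike times must be finite", call. = FALSE)
  if (is.null(delta_ref)) {
    d <- mean(apply(spikes, 1L, function(s) mean(diff(s))))
    delta_ref <- if (is.finite(d) && d > 0) d else params$tau_I
  }
  if (is.null(grid)) grid <- estimation_grid(params, delta_ref)
  out <- estimate_map_batch(spikes, params, grid)
  if (vec_in) {
    res <- as.list(out[1L, ])
    class(res) <- "estimation_result"
    return(res)
  }
  out
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("MAP estimate: t1 = %.5f s, delta = %.5f s (log posterior %.3f)\n",
              x$t1_est, x$delta_est, x$log_posterior))
  invisible(x)
}

# Expected-loss-optimal lag added to the estimated last-beat time, before
# the better-early-than-late shift is subtracted. Closed forms:
# Dirac -> posterior mode (n-1) tau_I; quadratic -> mean n tau_I;
# absolute -> Gamma median. The margin loss has an expected value linear
# in the prediction, so it is minimized on the boundary of the documented
# window [-3 tau_I, +6 tau_I] around the estimated last-beat time.
loss_optimal_lag <- function(params, t_last = NULL) {
  with(params, switch(loss_kind,
    dirac = (n_shape - 1) * tau_I,
    quadratic = n_shape * tau_I,
    absolute = tau_I * qgamma(0.5, shape = n_shape),
    margin = {
      if (is.null(t_last))
        stop("margin loss needs the estimated last-beat time", call. = FALSE)
      # expected loss 1 - v * E[s'] / tau_S^2 in the shifted prediction
      # v = s* + tau_E; decreasing in v iff E[s'] > 0
      ifelse(t_last + n_shape * tau_I > 0, 6 * tau_I, -3 * tau_I)
    }))
}

#' Predict the time of the last spike
#'
#' Stage two of the observer: from the estimated first-beat time and
#' interval, the last beat is extrapolated to
#' `t_N = t1_est + (n_beats - 1) * delta_est` and the loss-optimal
#' prediction of the last spike is formed. For the Dirac loss this is the
#' posterior mode (`t_N + (n_shape - 1) tau_I`), for the quadratic loss
#' the posterior mean (`t_N + n_shape tau_I`), for the absolute loss the
#' posterior median (`t_N + ` Gamma median); for the margin loss the
#' expected loss is linear in the prediction and is minimized over the
#' bounded window `t_N + [-3, +6] tau_I` (applied to the shifted
#' prediction). The better-early-than-late shift `tau_E` is subtracted in
#' every case, moving predictions earlier.
#'
#' @param t1_est,delta_est Stage-one estimates in seconds (vectorized).
#' @param n_beats Number of beats N (>= 2).
#' @param params An [observer_params()] object.
#' @param method `"closed_form"` (default) or `"numeric"` (explicit
#'   expected-loss optimization by quadrature; scalar inputs only, used
#'   for verification).
#' @return Predicted last-spike time(s) in seconds.
#' @export
predict_last_spike <- function(t1_est, delta_est, n_beats, params,
                               method = c("closed_form", "numeric")) {
  validate_observer_params(params)
  method <- match.arg(method)
  if (any(n_beats < 2)) stop("'n_beats' must be >= 2", call. = FALSE)
  t_last <- t1_est + (n_beats - 1) * delta_est
  if (method == "closed_form")
    return(t_last + loss_optimal_lag(params, t_last) - params$tau_E)
  vapply(t_last, predict_numeric_one, numeric(1L), params = params)
}

# Numeric expected-loss optimization for one estimated last-beat time.
# Independent of the closed forms above: direct optimize()/integrate().
predict_numeric_one <- function(t_last, params) {
  tau_I <- params$tau_I
  n <- params$n_shape
  dens <- function(x) dgamma(x - t_last, shape = n, scale = tau_I)
  if (params$loss_kind == "dirac") {
    # posterior-mode maximization of the spike density
    opt <- optimize(dens, c(t_last, t_last + max(5, 3 * n) * tau_I),
                    maximum = TRUE, tol = 1e-10)
    return(opt$maximum - params$tau_E)
  }
  # the optimization variable is the shifted prediction v = s* + tau_E;
  # the margin loss uses the documented bounded window on v
  window <- if (params$loss_kind == "margin") {
    c(t_last - 3 * tau_I, t_last + 6 * tau_I)
  } else {
    c(t_last - 5 * n * tau_I, t_last + 10 * n * tau_I)
  }
  expected_loss <- function(v) {
    integrate(function(x) loss_value(params$loss_kind, v - params$tau_E,
                                     x, params) * dens(x),
              lower = t_last, upper = t_last + 40 * n * tau_I,
              rel.tol = 1e-9)$value
  }
  opt <- optimize(Vectorize(expected_loss), window, tol = 1e-9)
  v <- opt$minimum
  if (params$loss_kind == "margin") {
    # linear expected loss optimizes on a window edge
    v <- window[which.min(vapply(window, expected_loss, numeric(1L)))]
  }
  v - params$tau_E
}

#' Two-alternative forced-choice decision
#'
#' The observer answers "late" when the predicted last spike precedes the
#' actual one (the beat seemed to arrive later than expected) and "early"
#' in the opposite case. Exact ties are broken by a fair coin flip drawn
#' from the current RNG stream.
#'
#' @param predicted_last_spike,actual_last_spike Times in seconds
#'   (vectorized, equal length).
#' @return Character vector of `"early"` / `"late"`.
#' @examples
#' decide(1.0, 1.1) # "late"
#' decide(1.2, 1.1) # "early"
#' @export
decide <- function(predicted_last_spike, actual_last_spike) {
  stopifnot(length(predicted_last_spike) == length(actual_last_spike),
            all(is.finite(predicted_last_spike)),
            all(is.finite(actual_last_spike)))
  out <- ifelse(predicted_last_spike < actual_last_spike, "late", "early")
  ties <- predicted_last_spike == actual_last_spike
  if (any(ties))
    out[ties] <- ifelse(runif(sum(ties)) < 0.5, "early", "late")
  out
}

# Vectorized decision with pre-drawn tie-break uniforms (one per trial),
# so common-random-number simulation stays deterministic.
decide_batch <- function(predicted, actual, u_tie) {
  out <- ifelse(predicted < actual, "late", "early")
  ties <- predicted == actual
  if (any(ties)) out[ties] <- ifelse(u_tie[ties] < 0.5, "early", "late")
  out
}
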