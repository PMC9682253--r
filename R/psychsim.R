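#' Derive a per-condition random seed from a master seed
#'
#' Conditions get independent substreams keyed by (N, delta, rho), so
#' adding or removing conditions never perturbs the draws of another
#' condition. The key is an exact integer hash of the condition (delta
#' and rho resolved to 0.1 ms) mixed with the master seed, kept below
#' 2^31.
#'
#' @param master_seed Integer master seed.
#' @param n_beats,delta,rho Condition coordinates.
#' @return An integer seed in 1..2147483646.
#' @export
condition_seed <- function(master_seed, n_beats, delta, rho) {
  key <- round(delta * 1e4) * 1e7 + (round(rho * 1e4) + 5000) * 100 + n_beats
  s <- ((as.numeric(master_seed) %% 2147483647) * 16807) %% 2147483647
  as.integer((s + key) %% 2147483646) + 1L
}

# One condition's worth of simulated trials. Returns per-trial responses.
simulate_trials <- function(params, n_beats, delta, rho, n_mc, seed,
                            grid = NULL) {
  pattern <- generate_beat_times(n_beats, delta, rho)
  if (is.null(grid)) grid <- estimation_grid(params, delta)
  set.seed(seed)
  u <- matrix(runif(n_mc * n_beats), nrow = n_mc)
  u_tie <- runif(n_mc)
  lags <- qgamma(u, shape = params$n_shape, scale = params$tau_I)
  spikes <- matrix(pattern$times, n_mc, n_beats, byrow = TRUE) + lags
  est <- estimate_map_batch(spikes[, -n_beats, drop = FALSE], params, grid)
  pred <- predict_last_spike(est$t1_est, est$delta_est, n_beats, params)
  resp <- decide_batch(pred, spikes[, n_beats], u_tie)
  correct <- if (rho < 0) resp == "early"
             else if (rho > 0) resp == "late"
             else rep(NA, n_mc)
  list(response = resp, correct = correct, est = est, predicted = pred,
       actual = spikes[, n_beats])
}

#' Simulate one experimental condition
#'
#' Runs `n_mc` independent trials of the full observer loop: sample one
#' spike per beat, estimate (t1, Delta) from the first N - 1 spikes,
#' predict the last spike under the configured loss, and compare with the
#' actual last spike. A response is correct when the final beat was early
#' (`rho < 0`) and the observer answered "early", or late (`rho > 0`)
#' and the observer answered "late"; correctness is undefined at
#' `rho = 0`.
#'
#' @param params An [observer_params()] object.
#' @param n_beats,delta,rho Condition coordinates.
#' @param n_mc Number of Monte-Carlo trials (default 1000).
#' @param seed Master seed; the condition substream is derived via
#'   [condition_seed()].
#' @param keep_trials If `TRUE`, return the per-trial data frame instead
#'   of the aggregated record.
#' @return A one-row data frame with columns `n_beats`, `delta_s`, `rho`,
#'   `trials`, `n_late`, `n_early`, `n_correct` (`NA` at `rho = 0`),
#'   `p_correct`, `p_late`; or per-trial rows when `keep_trials = TRUE`.
#' @export
simulate_condition <- function(params, n_beats, delta, rho, n_mc = 1000L,
                               seed = 1L, keep_trials = FALSE) {
  validate_observer_params(params)
  if (n_mc < 1) stop("'n_mc' must be >= 1", call. = FALSE)
  tr <- simulate_trials(params, n_beats, delta, rho, n_mc,
                        condition_seed(seed, n_beats, delta, rho))
  if (keep_trials) {
    return(data.frame(n_beats = n_beats, delta_s = delta, rho = rho,
                      trial = seq_len(n_mc), response = tr$response,
                      correct = tr$correct))
  }
  n_late <- sum(tr$response == "late")
  data.frame(n_beats = n_beats, delta_s = delta, rho = rho,
             trials = n_mc, n_late = n_late, n_early = n_mc - n_late,
             n_correct = if (rho == 0) NA_integer_ else sum(tr$correct),
             p_correct = if (rho == 0) NA_real_ else mean(tr$correct),
             p_late = n_late / n_mc)
}

#' Simulate a full experimental design
#'
#' Applies [simulate_condition()] to every condition of a design grid,
#' with per-condition substreams derived from the master seed.
#'
#' @param params An [observer_params()] object.
#' @param design A [build_design()] grid (or any data frame with columns
#'   `n_beats`, `delta_s`, `rho`).
#' @param n_mc Monte-Carlo trials per condition.
#' @param seed Master seed.
#' @return A psychometric surface: data frame with one row per condition
#'   (columns as in [simulate_condition()]).
#' @export
simulate_design <- function(params, design, n_mc = 1000L, seed = 1L) {
  stopifnot(is.data.frame(design),
            all(c("n_beats", "delta_s", "rho") %in% names(design)))
  rows <- lapply(seq_len(nrow(design)), function(i) {
    simulate_condition(params, design$n_beats[i], design$delta_s[i],
                       design$rho[i], n_mc = n_mc, seed = seed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Late-minus-Early response excess at zero deviation
#'
#' For beat patterns whose final interval carries no deviation
#' (`rho = 0`) there is no correct answer; any imbalance between "late"
#' and "early" responses measures the observer's timing bias. Negative
#' excess means an early bias (the last beat is predicted later than it
#' arrives).
#'
#' @param surface A psychometric surface from [simulate_design()] or
#'   [response_surface()].
#' @return Data frame with one row per (N, delta): `n_beats`, `delta_s`,
#'   `trials`, `excess_late` (= late - early counts) and `p_late`.
#' @export
bias_table <- function(surface) {
  stopifnot(is.data.frame(surface))
  z <- surface[surface$rho == 0, , drop = FALSE]
  if (!nrow(z))
    stop("surface contains no rho = 0 conditions", call. = FALSE)
  out <- z[, c("n_beats", "delta_s", "trials")]
  out$excess_late <- z$n_late - z$n_early
  out$p_late <- z$p_late
  out <- out[order(out$n_beats, out$delta_s), ]
  rownames(out) <- NULL
  out
}

#' Write / read a psychometric surface as CSV
#'
#' Columns: `n_beats, delta_s, rho, trials, n_late, n_early, n_correct,
#' p_correct, p_late` (`n_correct`/`p_correct` empty at `rho = 0`).
#'
#' @param surface Surface data frame.
#' @param path Output file path.
#' @return `write_surface` invisibly returns `path`; `read_surface`
#'   returns the surface data frame.
#' @export
write_surface <- function(surface, path) {
  cols <- c("n_beats", "delta_s", "rho", "trials", "n_late", "n_early",
            "n_correct", "p_correct", "p_late")
  stopifnot(all(cols %in% names(surface)))
  write.csv(surface[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
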