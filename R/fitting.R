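#' Pearson chi-square between predicted rates and observed counts
#'
#' Each condition contributes two cells (successes and failures):
#' `(O - E)^2/E + (O' - E')^2/E'` with `E = p * n`. Predicted
#' proportions are clamped away from 0 and 1 (to `1/(2 * clamp_n)`) so a
#' finite-Monte-Carlo prediction of exactly 0 or 1 cannot produce a
#' division by zero.
#'
#' @param predicted_p Predicted success proportions per condition.
#' @param observed_k Observed success counts per condition.
#' @param trials Trials per condition (all > 0).
#' @param clamp_n Effective sample size behind the predictions, used for
#'   the clamp (default 1000).
#' @return The chi-square statistic (dimensionless).
#' @examples
#' chi_square(0.5, 10, 18) # (10-9)^2/9 + (8-9)^2/9 = 0.2222
#' @export
chi_square <- function(predicted_p, observed_k, trials, clamp_n = 1000) {
  stopifnot(length(predicted_p) == length(observed_k),
            length(observed_k) == length(trials))
  if (any(trials <= 0)) stop("all conditions need trials > 0", call. = FALSE)
  if (any(observed_k < 0 | observed_k > trials))
    stop("observed counts must lie in [0, trials]", call. = FALSE)
  eps <- 1 / (2 * clamp_n)
  p <- pmin(pmax(predicted_p, eps), 1 - eps)
  sum((observed_k - trials * p)^2 / (trials * p * (1 - p)))
}

#' Degrees of freedom and p-value of the goodness-of-fit test
#'
#' `df = n_conditions - n_free_params - 1`; the p-value is the upper
#' tail of the chi-square distribution at `df`. On the canonical grid
#' (96 deviated conditions) this gives 89 degrees of freedom for the
#' six-parameter margin loss and 90 for the five-parameter losses.
#'
#' @param chi2 Chi-square statistic.
#' @param n_conditions Number of fitted conditions.
#' @param n_free_params Number of free observer parameters.
#' @return List with `df` and `p_value`.
#' @examples
#' goodness_of_fit(100, 96, 6)$df # 89
#' @export
goodness_of_fit <- function(chi2, n_conditions, n_free_params) {
  df <- n_conditions - n_free_params - 1
  if (df < 1) stop("non-positive degrees of freedom", call. = FALSE)
  list(df = as.integer(df),
       p_value = pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Number of free parameters of a loss variant
#'
#' The margin loss uses six parameters (its scale `tau_S` is active);
#' the Dirac, quadratic and absolute losses use five. Disabling the
#' prior removes its two parameters.
#'
#' @param loss_kind Loss name.
#' @param prior_enabled Whether the interval prior is active.
#' @return Integer parameter count.
#' @export
n_free_params <- function(loss_kind, prior_enabled = TRUE) {
  k <- if (loss_kind == "margin") 6L else 5L
  if (!prior_enabled) k <- k - 2L
  k
}

# Coordinate descriptors for the coordinate-descent fit. Timescales move
# on a log scale; shapes and the early shift on a linear scale with
# floors matching their domains. The impulse response is searched in the
# decorrelated coordinates (mu_I, n) with mu_I = n * tau_I the mean
# beat-to-spike lag: shape and time constant trade off along a sharp
# chi-square ridge, and a line search on n at fixed mean lag crosses
# that ridge where one at fixed tau_I stalls.
fit_coordinates <- function(loss_kind, prior_enabled) {
  coords <- list(
    list(name = "mu_I", scale = "log"),
    list(name = "n_shape", scale = "linear", floor = 1, unit = 1),
    list(name = "tau_Delta", scale = "log"),
    list(name = "sigma", scale = "linear", floor = 0.05, unit = 0.5),
    list(name = "tau_E", scale = "linear", floor = 0, unit = 0.005),
    list(name = "tau_S", scale = "log"))
  keep <- vapply(coords, function(co) {
    if (co$name == "tau_S") loss_kind == "margin"
    else if (co$name %in% c("tau_Delta", "sigma")) prior_enabled
    else TRUE
  }, logical(1L))
  coords[keep]
}

# Read/write the fit coordinates on an observer_params object.
coord_get <- function(params, name) {
  if (name == "mu_I") params$n_shape * params$tau_I else params[[name]]
}

coord_set <- function(params, name, value) {
  if (name == "mu_I") {
    params$tau_I <- value / params$n_shape
  } else if (name == "n_shape") {
    mu <- params$n_shape * params$tau_I
    params$n_shape <- value
    params$tau_I <- mu / value
  } else {
    params[[name]] <- value
  }
  params
}

# Aggregate observed data to per-condition correct counts at rho != 0.
observed_correct_counts <- function(observed) {
  if ("response" %in% names(observed)) {
    observed <- response_surface(observed)
  }
  need <- c("n_beats", "delta_s", "rho", "trials", "n_correct")
  if (!all(need %in% names(observed)))
    stop("observed data must be a response table or a surface with ",
         "columns ", paste(need, collapse = ", "), call. = FALSE)
  obs <- observed[observed$rho != 0, need, drop = FALSE]
  if (!nrow(obs)) stop("no deviated (rho != 0) conditions to fit",
                       call. = FALSE)
  if (any(obs$trials <= 0)) stop("zero-trial condition in observed data",
                                 call. = FALSE)
  obs[order(obs$n_beats, obs$delta_s, obs$rho), ]
}

# Model-predicted probability of a correct response for each condition
# row, evaluated with common random numbers under `seed`.
predicted_correct <- function(params, conditions, n_mc, seed) {
  vapply(seq_len(nrow(conditions)), function(i) {
    tr <- simulate_trials(params, conditions$n_beats[i],
                          conditions$delta_s[i], conditions$rho[i], n_mc,
                          condition_seed(seed, conditions$n_beats[i],
                                         conditions$delta_s[i],
                                         conditions$rho[i]))
    mean(tr$correct)
  }, numeric(1L))
}

# Golden-section minimization of f on [lo, hi] to absolute tolerance tol.
golden_search <- function(f, lo, hi, tol) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 <= f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    }
  }
  if (f1 <= f2) list(x = x1, f = f1) else list(x = x2, f = f2)
}

#' Fit observer parameters to 2AFC counts by coordinate descent
#'
#' Minimizes the Pearson chi-square between model-predicted and observed
#' per-condition correct counts (deviated conditions only) by cycling
#' through the free parameters with a bracketed golden-section line
#' search per coordinate. The stochastic objective is made deterministic
#' by common random numbers: every evaluation reuses the same
#' per-condition substreams derived from `seed`, and spikes are generated
#' through the Gamma quantile function so the objective is continuous in
#' the impulse-response parameters. Only strict improvements are
#' accepted.
#'
#' @param observed A response table (with a `response` column) or a
#'   psychometric surface with per-condition `n_correct` and `trials`.
#' @param loss_kind Loss function to fit.
#' @param init Initial [observer_params()]; defaults to the conventional
#'   starting point (`observer_params()` with the requested loss).
#' @param n_mc Monte-Carlo trials per condition per objective evaluation.
#' @param seed Seed for the common random numbers.
#' @param max_sweeps Maximum coordinate sweeps (default 20).
#' @param coord_tol Relative line-search tolerance per coordinate.
#' @param bracket_expansions Maximum number of x3 bracket widenings.
#' @return An object of class `beat_fit`: `params` at the optimum,
#'   `chi2`, `df`, `p_value`, the acceptance `trace` (one row per
#'   accepted step, chi-square non-increasing), `seed`, `n_mc`,
#'   `converged`.
#' @export
coordinate_descent_fit <- function(observed, loss_kind = "absolute",
                                   init = NULL, n_mc = 250L, seed = 1L,
                                   max_sweeps = 20L, coord_tol = 1e-2,
                                   bracket_expansions = 4L) {
  if (is.null(init)) init <- observer_params(loss_kind = loss_kind)
  stopifnot(inherits(init, "observer_params"))
  if (init$loss_kind != loss_kind)
    init <- update_params(init, loss_kind = loss_kind)
  obs <- observed_correct_counts(observed)
  coords <- fit_coordinates(loss_kind, init$prior_enabled)

  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  objective <- function(params) {
    key <- paste(sprintf("%.12g", c(params$tau_I, params$n_shape,
                                    params$tau_Delta, params$sigma,
                                    params$tau_E, params$tau_S)),
                 collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- predicted_correct(params, obs, n_mc, seed)
    val <- chi_square(p, obs$n_correct, obs$trials, clamp_n = n_mc)
    if (!is.finite(val)) stop("non-finite chi-square objective",
                              call. = FALSE)
    n_evals <<- n_evals + 1L
    cache[[key]] <- val
    val
  }

  cur <- init
  f_cur <- objective(cur)
  trace <- list(trace_row(0L, "init", cur, f_cur))
  converged <- FALSE

  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (co in coords) {
      x0 <- coord_get(cur, co$name)
      if (co$scale == "log") {
        u0 <- log(x0)
        to_x <- exp
        tol <- coord_tol
        h <- log(1.5)
      } else {
        u0 <- x0
        to_x <- function(u) max(co$floor, u)
        tol <- coord_tol * max(abs(x0), co$unit)
        h <- max(0.5 * abs(x0), co$unit)
      }
      f_u <- function(u) objective(coord_set(cur, co$name, to_x(u)))
      hl <- h; hr <- h
      lo <- u0 - hl; hi <- u0 + hr
      f_lo <- f_u(lo); f_hi <- f_u(hi)
      exp_left <- 0L; exp_right <- 0L
      while (f_lo < min(f_cur, f_hi) && exp_left < bracket_expansions) {
        hl <- hl * 3; lo <- u0 - hl; f_lo <- f_u(lo)
        exp_left <- exp_left + 1L
      }
      while (f_hi < min(f_cur, f_lo) && exp_right < bracket_expansions) {
        hr <- hr * 3; hi <- u0 + hr; f_hi <- f_u(hi)
        exp_right <- exp_right + 1L
      }
      best <- golden_search(f_u, lo, hi, tol)
      if (best$f < f_cur) {
        cur <- coord_set(cur, co$name, to_x(best$x))
        f_cur <- best$f
        improved <- TRUE
        trace <- c(trace, list(trace_row(sweep, co$name, cur, f_cur)))
      }
    }
    if (!improved) { converged <- TRUE; break }
  }

  trace <- do.call(rbind, trace)
  rownames(trace) <- NULL
  gof <- goodness_of_fit(f_cur, nrow(obs),
                         n_free_params(loss_kind, init$prior_enabled))
  structure(list(params = cur, chi2 = f_cur, df = gof$df,
                 p_value = gof$p_value, trace = trace, seed = seed,
                 n_mc = n_mc, n_conditions = nrow(obs),
                 n_evals = n_evals, converged = converged),
            class = "beat_fit")
}

trace_row <- function(sweep, coordinate, params, chi2) {
  data.frame(sweep = sweep, coordinate = coordinate,
             tau_I = params$tau_I, n_shape = params$n_shape,
             tau_Delta = params$tau_Delta, sigma = params$sigma,
             tau_E = params$tau_E, tau_S = params$tau_S, chi2 = chi2)
}

#' @export
print.beat_fit <- function(x, ...) {
  cat(sprintf("observer fit (%s loss): chi2 = %.2f on %d df (p = %.3g)\n",
              x$params$loss_kind, x$chi2, x$df, x$p_value))
  cat(sprintf("  %d conditions, n_mc = %d, %d objective evaluations, %s\n",
              x$n_conditions, x$n_mc, x$n_evals,
              if (x$converged) "converged" else "sweep limit reached"))
  print(x$params)
  invisible(x)
}

#' Serialize a fit result
#'
#' Writes the fitted parameters, chi-square, degrees of freedom, p-value
#' and options as JSON, and the acceptance trace as CSV.
#'
#' @param fit A `beat_fit` object.
#' @param json_path,trace_path Output paths (either may be `NULL`).
#' @return Invisibly, the fit.
#' @export
write_fit <- function(fit, json_path = NULL, trace_path = NULL) {
  stopifnot(inherits(fit, "beat_fit"))
  if (!is.null(json_path)) {
    rec <- list(params = unclass(fit$params), chi2 = fit$chi2,
                df = fit$df, p_value = fit$p_value, seed = fit$seed,
                n_mc = fit$n_mc, n_conditions = fit$n_conditions,
                converged = fit$converged)
    jsonlite::write_json(rec, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(trace_path))
    write.csv(fit$trace, trace_path, row.names = FALSE)
  invisible(fit)
}
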