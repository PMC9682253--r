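#' Generate an isochronic beat pattern with a deviated final interval
#'
#' Beat times start at 0 by convention (the origin of a repeating pattern
#' is arbitrary) and are spaced `delta` seconds apart, except the final
#' interval which is `delta * (1 + rho)`.
#'
#' @param n_beats Number of beats N (integer >= 2).
#' @param delta Inter-beat interval in seconds (> 0).
#' @param rho Relative deviation of the last interval (dimensionless,
#'   > -1 so the final interval stays positive).
#' @return An object of class `beat_pattern` with fields `n_beats`,
#'   `delta`, `rho` and `times` (length-N numeric, strictly increasing).
#' @examples
#' generate_beat_times(3, 0.3, 0.1)$times # 0.00 0.30 0.63
#' @export
generate_beat_times <- function(n_beats, delta, rho = 0) {
  if (!is.numeric(n_beats) || length(n_beats) != 1L || n_beats < 2 ||
      n_beats != round(n_beats))
    stop("'n_beats' must be an integer >= 2", call. = FALSE)
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0)
    stop("'delta' must be a positive number of seconds", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= -1)
    stop("'rho' must be > -1 (the final interval must be positive)",
         call. = FALSE)
  n_beats <- as.integer(n_beats)
  times <- c(seq.int(0L, n_beats - 2L) * delta,
             (n_beats - 2L) * delta + delta * (1 + rho))
  structure(list(n_beats = n_beats, delta = delta, rho = rho, times = times),
            class = "beat_pattern")
}

#' @export
print.beat_pattern <- function(x, ...) {
  cat(sprintf("beat pattern: N = %d, delta = %g s, rho = %+g\n",
              x$n_beats, x$delta, x$rho))
  cat("  times:", paste(signif(x$times, 6), collapse = " "), "\n")
  invisible(x)
}

# Table of named design presets. "canonical" is the grid shared by most
# subjects of the reference experiment; "subject1"/"subject2" add a 0.9 s
# interval (subject1 also denser deviations).
design_presets <- function() {
  list(
    canonical = list(
      n_values = c(3, 4, 6, 9),
      delta_values = c(0.15, 0.3, 0.6, 1.2),
      rho_values = c(-0.15, -0.1, -0.05, 0, 0.05, 0.1, 0.15)),
    subject1 = list(
      n_values = c(3, 4, 6, 9),
      delta_values = c(0.15, 0.3, 0.6, 0.9, 1.2),
      rho_values = c(-0.15, -0.125, -0.1, -0.075, -0.05, 0,
                     0.05, 0.075, 0.1, 0.125, 0.15)),
    subject2 = list(
      n_values = c(3, 4, 6, 9),
      delta_values = c(0.15, 0.3, 0.6, 0.9, 1.2),
      rho_values = c(-0.15, -0.1, -0.05, 0, 0.05, 0.1, 0.15))
  )
}

#' Build a factorial experimental design grid
#'
#' Enumerates every (N, delta, rho) condition of a factorial 2AFC design,
#' either from a named preset (`"canonical"`: 4 x 4 x 7 = 112 conditions;
#' `"subject1"`, `"subject2"`: extended grids with a 0.9 s interval) or
#' from explicit value sets.
#'
#' @param design Name of a preset, ignored when explicit sets are given.
#' @param n_values,delta_values,rho_values Optional explicit value sets.
#' @param reps Planned repetitions per condition (default 18).
#' @return A data frame of class `design_grid` with columns `n_beats`,
#'   `delta_s`, `rho`, one row per condition, and attribute `reps`.
#' @examples
#' d <- build_design("canonical")
#' nrow(d)                  # 112
#' sum(d$rho != 0)          # 96
#' @export
build_design <- function(design = "canonical", n_values = NULL,
                         delta_values = NULL, rho_values = NULL,
                         reps = 18L) {
  explicit <- !is.null(n_values) || !is.null(delta_values) ||
    !is.null(rho_values)
  if (explicit) {
    if (is.null(n_values) || is.null(delta_values) || is.null(rho_values))
      stop("give all of 'n_values', 'delta_values', 'rho_values' or none",
           call. = FALSE)
  } else {
    presets <- design_presets()
    if (!is.character(design) || length(design) != 1L ||
        !design %in% names(presets))
      stop("unknown design preset '", design, "'; available: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    p <- presets[[design]]
    n_values <- p$n_values
    delta_values <- p$delta_values
    rho_values <- p$rho_values
  }
  if (!length(n_values) || !length(delta_values) || !length(rho_values))
    stop("design value sets must be non-empty", call. = FALSE)
  if (any(n_values < 3) || any(n_values != round(n_values)))
    stop("'n_values' must be integers >= 3 (estimation needs two spikes)",
         call. = FALSE)
  if (any(delta_values <= 0))
    stop("'delta_values' must be positive seconds", call. = FALSE)
  if (anyDuplicated(rho_values))
    stop("'rho_values' must be unique", call. = FALSE)
  if (any(rho_values <= -1))
    stop("'rho_values' must be > -1", call. = FALSE)
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1 ||
      reps != round(reps))
    stop("'reps' must be a positive integer", call. = FALSE)
  grid <- expand.grid(rho = sort(rho_values),
                      delta_s = sort(unique(delta_values)),
                      n_beats = sort(unique(as.integer(n_values))),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("n_beats", "delta_s", "rho")]
  rownames(grid) <- NULL
  attr(grid, "reps") <- as.integer(reps)
  class(grid) <- c("design_grid", "data.frame")
  grid
}

#' Count conditions in a design grid
#'
#' @param design A `design_grid`.
#' @param nonzero_rho If `TRUE`, count only conditions with a deviated
#'   final interval (the cells entering the chi-square fit).
#' @return Integer condition count.
#' @export
n_conditions <- function(design, nonzero_rho = FALSE) {
  stopifnot(is.data.frame(design))
  if (nonzero_rho) sum(design$rho != 0) else nrow(design)
}
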