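#' Specification of a synthetic 2AFC cohort
#'
#' Describes a cohort of simulated subjects sharing an experimental
#' design: a base observer, per-parameter inter-subject spread, an
#' optional lapse rate (probability of replacing a response with a fair
#' coin flip, emulating decision noise the ideal observer lacks), and
#' repetitions per condition. Timescale parameters (`tau_I`,
#' `tau_Delta`, `tau_E`, `tau_S`) are perturbed multiplicatively
#' (lognormal, preserving positivity); the shape parameters (`n_shape`,
#' `sigma`) additively with resampling until they fall back in their
#' valid domain.
#'
#' @param n_subjects Number of subjects (default 7, the reference cohort
#'   size).
#' @param base_params Base [observer_params()]; defaults to
#'   [standard_observer_params()].
#' @param inter_subject_sd Named numeric vector of spreads. For
#'   timescales the value is the sdlog of the multiplicative
#'   perturbation; for shapes the additive sd. Missing names default
#'   to 0.
#' @param lapse_rate Lapse probability in [0, 0.5); default 0 (the pure
#'   model observer).
#' @param design A [build_design()] grid.
#' @param reps Trials per condition per subject (default: the design's
#'   `reps` attribute).
#' @param master_seed Integer master seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 7L,
                        base_params = standard_observer_params(),
                        inter_subject_sd = c(tau_I = 0.2, tau_Delta = 0.25,
                                             tau_E = 0.3, n_shape = 0.15,
                                             sigma = 0.15, tau_S = 0),
                        lapse_rate = 0, design = build_design("canonical"),
                        reps = NULL, master_seed = 1L) {
  stopifnot(n_subjects >= 1, inherits(base_params, "observer_params"))
  if (!is.numeric(lapse_rate) || lapse_rate < 0 || lapse_rate >= 0.5)
    stop("'lapse_rate' must lie in [0, 0.5)", call. = FALSE)
  known <- c("tau_I", "tau_Delta", "tau_E", "tau_S", "n_shape", "sigma")
  bad <- setdiff(names(inter_subject_sd), known)
  if (length(bad))
    stop("unknown parameter(s) in 'inter_subject_sd': ",
         paste(bad, collapse = ", "), call. = FALSE)
  sdv <- setNames(numeric(length(known)), known)
  sdv[names(inter_subject_sd)] <- inter_subject_sd
  if (is.null(reps)) reps <- attr(design, "reps")
  stopifnot(is.numeric(reps), reps >= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 base_params = base_params, inter_subject_sd = sdv,
                 lapse_rate = lapse_rate, design = design,
                 reps = as.integer(reps),
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

subject_seed <- function(master_seed, i) {
  s <- ((as.numeric(master_seed) %% 2147483647) * 48271) %% 2147483647
  as.integer((s + i * 2654435) %% 2147483646) + 1L
}

# Draw one subject's parameters around the base set.
perturb_params <- function(base, sdv) {
  draw_pos <- function(x, sd) if (sd > 0) x * exp(rnorm(1L, 0, sd)) else x
  draw_floor <- function(x, sd, floor) {
    if (sd <= 0) return(x)
    for (i in 1:100) {
      y <- x + rnorm(1L, 0, sd)
      if (y >= floor) return(y)
    }
    floor
  }
  update_params(base,
    tau_I = draw_pos(base$tau_I, sdv[["tau_I"]]),
    tau_Delta = draw_pos(base$tau_Delta, sdv[["tau_Delta"]]),
    tau_E = draw_pos(base$tau_E, sdv[["tau_E"]]),
    tau_S = draw_pos(base$tau_S, sdv[["tau_S"]]),
    n_shape = draw_floor(base$n_shape, sdv[["n_shape"]], 1),
    sigma = draw_floor(base$sigma, sdv[["sigma"]], 0.05))
}

#' Generate one synthetic subject's response table
#'
#' Simulates `reps` trials per design condition through the observer's
#' single-trial path, optionally replaces each response by a fair coin
#' flip with probability `lapse_rate`, and arranges the trials the way a
#' session would: conditions blocked by the number of beats, randomized
#' order within each block.
#'
#' @param params The subject's [observer_params()].
#' @param design A [build_design()] grid.
#' @param reps Trials per condition.
#' @param lapse_rate Lapse probability in [0, 0.5).
#' @param seed Integer seed (all of this subject's randomness derives
#'   from it).
#' @param subject_id Identifier written in the table.
#' @return A response table: data frame with columns `subject_id`,
#'   `n_beats`, `delta_s`, `rho`, `response`, `session`.
#' @export
generate_subject <- function(params, design, reps = 18L, lapse_rate = 0,
                             seed = 1L, subject_id = "S1") {
  validate_observer_params(params)
  stopifnot(is.data.frame(design), reps >= 1,
            lapse_rate >= 0, lapse_rate < 0.5)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    tr <- simulate_condition(params, design$n_beats[i], design$delta_s[i],
                             design$rho[i], n_mc = reps, seed = seed,
                             keep_trials = TRUE)
    tr$session <- paste0("N", design$n_beats[i])
    tr
  })
  tab <- do.call(rbind, rows)
  n <- nrow(tab)
  set.seed(subject_seed(seed, 999983L))
  lapse <- runif(n) < lapse_rate
  coin <- ifelse(runif(n) < 0.5, "early", "late")
  tab$response[lapse] <- coin[lapse]
  ord <- order(tab$n_beats, runif(n))
  tab <- tab[ord, ]
  data.frame(subject_id = subject_id, n_beats = tab$n_beats,
             delta_s = tab$delta_s, rho = tab$rho,
             response = tab$response, session = tab$session,
             row.names = NULL)
}

#' Generate a synthetic cohort with a ground-truth manifest
#'
#' Draws per-subject observer parameters around the base set and
#' simulates each subject's full response table. The manifest records
#' every subject's true parameters and seed, so downstream fits can be
#' scored against the generating truth.
#'
#' @param spec A [cohort_spec()].
#' @return List with `tables` (named list of response tables) and
#'   `manifest` (cohort spec echo plus per-subject truth).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  tables <- list()
  subjects <- list()
  for (i in seq_len(spec$n_subjects)) {
    sid <- sprintf("S%d", i)
    seed_i <- subject_seed(spec$master_seed, i)
    set.seed(seed_i)
    p_i <- perturb_params(spec$base_params, spec$inter_subject_sd)
    tables[[sid]] <- generate_subject(p_i, spec$design, spec$reps,
                                      spec$lapse_rate, seed = seed_i,
                                      subject_id = sid)
    subjects[[sid]] <- list(subject_id = sid, seed = seed_i,
                            params = unclass(p_i))
  }
  manifest <- list(n_subjects = spec$n_subjects,
                   base_params = unclass(spec$base_params),
                   inter_subject_sd = as.list(spec$inter_subject_sd),
                   lapse_rate = spec$lapse_rate, reps = spec$reps,
                   master_seed = spec$master_seed, subjects = subjects)
  list(tables = tables, manifest = manifest)
}

#' Write / read response tables and the cohort manifest
#'
#' Response-table CSVs use the header
#' `subject_id,n_beats,delta_s,rho,response,session` with responses
#' written lowercase (`early`/`late`) and read case-insensitively.
#' `write_cohort` writes one CSV per subject plus `manifest.json`.
#'
#' @param table A response table.
#' @param path CSV path.
#' @return `read_response_table` returns the table; the writers return
#'   their path(s) invisibly.
#' @export
write_response_table <- function(table, path) {
  cols <- c("subject_id", "n_beats", "delta_s", "rho", "response",
            "session")
  stopifnot(all(cols %in% names(table)))
  out <- table[, cols]
  out$response <- tolower(out$response)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "n_beats", "delta_s", "rho", "response")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("response table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tab$response <- tolower(tab$response)
  bad <- !tab$response %in% c("early", "late")
  if (any(bad))
    stop("column 'response' contains values other than early/late",
         call. = FALSE)
  tab
}

#' @rdname write_response_table
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(is.list(cohort), !is.null(cohort$tables),
            !is.null(cohort$manifest))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (sid in names(cohort$tables)) {
    p <- file.path(dir, paste0(sid, ".csv"))
    write_response_table(cohort$tables[[sid]], p)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(cohort$manifest, mp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, mp))
}

#' @rdname write_response_table
#' @export
read_cohort_manifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"),
                      simplifyVector = FALSE)
}
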