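#' Binomial standard error of a proportion
#'
#' `sqrt(p(1-p)/n)` with `p = k/n`; the error bar attached to every
#' per-condition response proportion.
#'
#' @param k Success count (0 <= k <= n).
#' @param n Trial count (>= 1).
#' @return Standard error of the proportion.
#' @examples
#' binomial_se(9, 18) # 0.11785
#' @export
binomial_se <- function(k, n) {
  stopifnot(all(n >= 1), all(k >= 0), all(k <= n))
  p <- k / n
  sqrt(p * (1 - p) / n)
}

#' Two-sided exact binomial test
#'
#' Exact two-sided p-value by the minimum-likelihood method: the sum of
#' the probabilities of all outcomes no more probable than the observed
#' one under Binomial(n, p0). Delegates to [stats::binom.test()].
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability (0 < p0 < 1).
#' @return The two-sided p-value.
#' @examples
#' exact_binomial_test(5, 5, 0.5) # 0.0625
#' @export
exact_binomial_test <- function(k, n, p0 = 0.5) {
  stopifnot(length(k) == 1L, length(n) == 1L, k >= 0, k <= n, n >= 1)
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1)
    stop("'p0' must lie strictly between 0 and 1", call. = FALSE)
  binom.test(k, n, p = p0, alternative = "two.sided")$p.value
}

#' Cohen's h effect size between two proportions
#'
#' `h = 2 asin(sqrt(p1)) - 2 asin(sqrt(p2))`, labelled by the usual
#' rule of thumb: negligible below 0.2, small in [0.2, 0.5), medium in
#' [0.5, 0.8), large at 0.8 and above (absolute value).
#'
#' @param p1,p2 Proportions in [0, 1].
#' @return List with `h` and `label`.
#' @examples
#' cohens_h(0.75, 0.5) # h = 0.5236, "medium"
#' @export
cohens_h <- function(p1, p2) {
  stopifnot(length(p1) == 1L, length(p2) == 1L)
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1)
    stop("proportions must lie in [0, 1]", call. = FALSE)
  h <- 2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))
  a <- abs(h)
  label <- if (a < 0.2) "negligible" else if (a < 0.5) "small"
           else if (a < 0.8) "medium" else "large"
  list(h = h, label = label)
}

#' Kendall rank-correlation trend test
#'
#' Kendall's tau (tau-b, tie-corrected) between an ordered condition
#' variable and a paired outcome, with a two-sided test of zero
#' association via [stats::cor.test()] (exact for small untied samples,
#' normal approximation under ties).
#'
#' @param x Condition values (length >= 3).
#' @param y Paired outcomes.
#' @return List with `tau`, `p_value` and `method = "tau-b"`.
#' @export
kendall_tau_trend <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("all-tied input has no defined trend", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = "kendall",
                                  alternative = "two.sided"))
  list(tau = unname(ct$estimate), p_value = ct$p.value, method = "tau-b")
}

#' Population prevalence of an effect
#'
#' Frequentist prevalence: the percentage of subjects showing the
#' effect, with binomial standard error, both on the percent scale.
#' Display values are rounded to integer percent; full precision is kept
#' in `percent` / `se_percent`.
#'
#' @param k Subjects showing the effect.
#' @param n Subjects tested (>= 1).
#' @return List with `percent`, `se_percent`, `display` (e.g.
#'   `"86% +/- 13%"`).
#' @examples
#' population_prevalence(6, 7) # 86% +/- 13%
#' @export
population_prevalence <- function(k, n) {
  stopifnot(length(k) == 1L, length(n) == 1L, n >= 1, k >= 0, k <= n)
  p <- k / n
  pct <- 100 * p
  se <- 100 * sqrt(p * (1 - p) / n)
  list(percent = pct, se_percent = se,
       display = sprintf("%d%% +/- %d%%", round(pct), round(se)))
}

#' Aggregate a response table into a psychometric surface
#'
#' Counts "late"/"early" responses (and correct responses at deviated
#' conditions) per (N, delta, rho) cell, pooling subjects unless
#' `by_subject = TRUE`.
#'
#' @param table A response table: data frame with columns `n_beats`,
#'   `delta_s`, `rho`, `response` (and optionally `subject_id`).
#' @param by_subject If `TRUE`, return a named list of per-subject
#'   surfaces.
#' @return A surface data frame (columns as in [simulate_condition()]),
#'   or a list of them.
#' @export
response_surface <- function(table, by_subject = FALSE) {
  stopifnot(is.data.frame(table),
            all(c("n_beats", "delta_s", "rho", "response") %in%
                  names(table)))
  resp <- tolower(table$response)
  if (!all(resp %in% c("early", "late")))
    stop("column 'response' may only contain 'early'/'late'",
         call. = FALSE)
  table$response <- resp
  if (by_subject) {
    stopifnot("subject_id" %in% names(table))
    return(lapply(split(table, table$subject_id), response_surface))
  }
  key <- interaction(table$n_beats, table$delta_s, table$rho, drop = TRUE)
  rows <- lapply(split(table, key), function(d) {
    n <- nrow(d)
    n_late <- sum(d$response == "late")
    rho <- d$rho[1L]
    correct <- if (rho < 0) d$response == "early"
               else if (rho > 0) d$response == "late" else NA
    data.frame(n_beats = d$n_beats[1L], delta_s = d$delta_s[1L],
               rho = rho, trials = n, n_late = n_late,
               n_early = n - n_late,
               n_correct = if (rho == 0) NA_integer_ else sum(correct),
               p_correct = if (rho == 0) NA_real_ else mean(correct),
               p_late = n_late / n)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$n_beats, out$delta_s, out$rho), ]
  rownames(out) <- NULL
  out
}

#' Median psychometric surface across subjects
#'
#' Per condition, the median across subjects of the per-subject response
#' proportions (`p_correct` at deviated conditions, `p_late`
#' everywhere). Conditions are matched on the intersection of the
#' subjects' grids.
#'
#' @param surfaces A list of per-subject surface data frames (e.g. from
#'   `response_surface(tab, by_subject = TRUE)`).
#' @return A surface-like data frame of medians with a `n_subjects`
#'   column.
#' @export
median_across_subjects <- function(surfaces) {
  stopifnot(is.list(surfaces), length(surfaces) >= 1)
  key_of <- function(s) paste(s$n_beats, s$delta_s, s$rho, sep = "|")
  shared <- Reduce(intersect, lapply(surfaces, key_of))
  if (!length(shared))
    stop("subjects share no experimental conditions", call. = FALSE)
  base <- surfaces[[1L]][match(shared, key_of(surfaces[[1L]])),
                         c("n_beats", "delta_s", "rho")]
  p_corr <- sapply(surfaces, function(s)
    s$p_correct[match(shared, key_of(s))])
  p_late <- sapply(surfaces, function(s)
    s$p_late[match(shared, key_of(s))])
  if (is.null(dim(p_corr))) p_corr <- matrix(p_corr, nrow = 1L)
  if (is.null(dim(p_late))) p_late <- matrix(p_late, nrow = 1L)
  base$n_subjects <- length(surfaces)
  base$p_correct <- apply(p_corr, 1L, median)
  base$p_late <- apply(p_late, 1L, median)
  out <- base[order(base$n_beats, base$delta_s, base$rho), ]
  rownames(out) <- NULL
  out
}

#' Pooled exact test over a group of conditions
#'
#' The trend-probing recipe for factorial 2AFC data: pool the trials of
#' the conditions selected by `grouping`, test the pooled success
#' proportion against `p0` with the exact binomial test, and report
#' Cohen's h between the group and its complement.
#'
#' @param table A response table (see [response_surface()]).
#' @param grouping Either a logical vector over the rows of `table` or a
#'   function mapping the table to one (e.g.
#'   `function(d) d$delta_s <= 0.3`).
#' @param p0 Null success probability.
#' @param outcome `"correct"` (success = correct answer; deviated rows
#'   only) or `"late"` (success = a "late" response).
#' @return List with group and complement counts and proportions, the
#'   exact `p_value` for the group against `p0`, and `h`/`h_label`
#'   between group and complement.
#' @export
pooled_condition_test <- function(table, grouping, p0 = 0.5,
                                  outcome = c("correct", "late")) {
  outcome <- match.arg(outcome)
  stopifnot(is.data.frame(table))
  sel <- if (is.function(grouping)) grouping(table) else grouping
  if (!is.logical(sel) || length(sel) != nrow(table))
    stop("'grouping' must give one logical per trial row", call. = FALSE)
  resp <- tolower(table$response)
  success <- if (outcome == "correct") {
    keep <- table$rho != 0
    ifelse(table$rho < 0, resp == "early", resp == "late") & keep
  } else {
    resp == "late"
  }
  use <- if (outcome == "correct") table$rho != 0 else rep(TRUE, nrow(table))
  g <- sel & use; cmp <- (!sel) & use
  if (!any(g) || !any(cmp))
    stop("grouping selects an empty group or complement", call. = FALSE)
  kg <- sum(success[g]); ng <- sum(g)
  kc <- sum(success[cmp]); nc <- sum(cmp)
  eff <- cohens_h(kg / ng, kc / nc)
  list(n_group = ng, k_group = kg, p_group = kg / ng,
       n_complement = nc, k_complement = kc, p_complement = kc / nc,
       p_value = exact_binomial_test(kg, ng, p0),
       h = eff$h, h_label = eff$label)
}
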