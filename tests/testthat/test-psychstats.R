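test_that("binomial standard errors follow sqrt(pq/n)", {
  expect_equal(binomial_se(9, 18), sqrt(0.25 / 18), tolerance = 1e-12)
  expect_equal(round(binomial_se(9, 18), 5), 0.11785)
  expect_equal(binomial_se(0, 18), 0)
  expect_equal(binomial_se(18, 18), 0)
  expect_error(binomial_se(1, 0))
})

test_that("exact binomial test reproduces enumeration for small n", {
  expect_equal(exact_binomial_test(5, 5, 0.5), 0.0625, tolerance = 1e-12)
  for (n in c(4, 6, 12)) expect_equal(exact_binomial_test(n / 2, n, 0.5), 1)
  for (n in 3:12) for (p0 in c(0.3, 0.5, 0.7)) for (k in 0:n) {
    expect_equal(exact_binomial_test(k, n, p0), oracle_binom_p(k, n, p0),
                 tolerance = 1e-10,
                 label = sprintf("k=%d n=%d p0=%.1f", k, n, p0))
  }
  expect_error(exact_binomial_test(1, 5, 0), "p0")
})

test_that("Cohen's h matches its arcsine form and labels", {
  expect_equal(cohens_h(0.3, 0.3)$h, 0)
  expect_identical(cohens_h(0.3, 0.3)$label, "negligible")
  h <- cohens_h(0.75, 0.5)
  expect_equal(h$h, 2 * asin(sqrt(0.75)) - 2 * asin(sqrt(0.5)),
               tolerance = 1e-12)
  expect_equal(round(h$h, 4), 0.5236)
  expect_identical(h$label, "medium")
  expect_identical(cohens_h(0.9, 0.3)$label, "large")
  expect_identical(cohens_h(0.6, 0.5)$label, "small")
  # antisymmetry and monotonicity in the first argument
  expect_equal(cohens_h(0.2, 0.7)$h, -cohens_h(0.7, 0.2)$h)
  hs <- vapply(seq(0.05, 0.95, by = 0.1),
               function(p) cohens_h(p, 0.4)$h, numeric(1L))
  expect_true(all(diff(hs) > 0))
  expect_error(cohens_h(1.2, 0.5), "proportions")
})

test_that("Kendall trend test matches pair counting, with and without ties", {
  expect_equal(kendall_tau_trend(1:4, c(2, 5, 7, 9))$tau, 1)
  expect_equal(kendall_tau_trend(1:4, c(9, 7, 5, 2))$tau, -1)
  set.seed(6)
  for (i in 1:20) {
    x <- sample(1:5, 8, replace = TRUE)
    y <- sample(1:5, 8, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau_trend(x, y)$tau, oracle_kendall_tau(x, y),
                 tolerance = 1e-10)
  }
  expect_error(kendall_tau_trend(c(1, 1, 1), c(2, 2, 2)), "tied")
  expect_error(kendall_tau_trend(1:2, 1:2), "3 pairs")
})

test_that("population prevalence reports percent with binomial error", {
  pr <- population_prevalence(6, 7)
  expect_equal(round(pr$percent), 86)
  expect_equal(round(pr$se_percent), 13)
  expect_identical(pr$display, "86% +/- 13%")
  expect_equal(population_prevalence(7, 7)$se_percent, 0)
  expect_equal(population_prevalence(0, 7)$percent, 0)
  # scale equivariance: same point estimate, smaller error
  a <- population_prevalence(3, 7); b <- population_prevalence(6, 14)
  expect_equal(a$percent, b$percent)
  expect_lt(b$se_percent, a$se_percent)
})

make_table <- function(cells) {
  # cells: list of (n_beats, delta_s, rho, n_late, n_early, subject)
  do.call(rbind, lapply(cells, function(cl) {
    data.frame(subject_id = cl$subject, n_beats = cl$n_beats,
               delta_s = cl$delta_s, rho = cl$rho,
               response = c(rep("late", cl$n_late),
                            rep("early", cl$n_early)),
               session = paste0("N", cl$n_beats))
  }))
}

test_that("response tables aggregate to correct psychometric surfaces", {
  tab <- make_table(list(
    list(subject = "S1", n_beats = 3, delta_s = 0.15, rho = 0.1,
         n_late = 12, n_early = 6),
    list(subject = "S1", n_beats = 3, delta_s = 0.15, rho = -0.1,
         n_late = 4, n_early = 14),
    list(subject = "S1", n_beats = 3, delta_s = 0.15, rho = 0,
         n_late = 3, n_early = 15)))
  s <- response_surface(tab)
  expect_equal(nrow(s), 3L)
  expect_equal(s$p_correct[s$rho == 0.1], 12 / 18)
  expect_equal(s$p_correct[s$rho == -0.1], 14 / 18)
  expect_true(is.na(s$p_correct[s$rho == 0]))
  expect_equal(s$p_late[s$rho == 0], 3 / 18)
  # responses are case-insensitive on read via read_response_table
  f <- tempfile(fileext = ".csv")
  tab2 <- tab; tab2$response <- toupper(tab2$response)
  write.csv(tab2, f, row.names = FALSE)
  expect_equal(response_surface(read_response_table(f))$n_late,
               s$n_late)
  unlink(f)
})

test_that("cross-subject medians are per-cell and order-invariant", {
  mk <- function(subject, n_late_pos) make_table(list(
    list(subject = subject, n_beats = 3, delta_s = 0.15, rho = 0.1,
         n_late = n_late_pos, n_early = 18 - n_late_pos)))
  surfs <- lapply(list(c("S1", 4), c("S2", 9), c("S3", 16)),
                  function(z) response_surface(mk(z[1], as.numeric(z[2]))))
  med <- median_across_subjects(surfs)
  expect_equal(med$p_correct, 9 / 18)
  expect_equal(median_across_subjects(surfs[c(3, 1, 2)])$p_correct,
               9 / 18)
  # a single subject is its own median
  one <- median_across_subjects(surfs[1])
  expect_equal(one$p_correct, 4 / 18)
})

test_that("pooled condition tests pool counts and size effects correctly", {
  tab <- make_table(list(
    list(subject = "S1", n_beats = 3, delta_s = 0.15, rho = 0.1,
         n_late = 4, n_early = 14),   # short interval, poor when late
    list(subject = "S1", n_beats = 3, delta_s = 1.2, rho = 0.1,
         n_late = 15, n_early = 3)))  # long interval, good when late
  res <- pooled_condition_test(tab, function(d) d$delta_s > 0.5,
                               outcome = "correct")
  expect_equal(res$n_group + res$n_complement, nrow(tab))
  expect_equal(res$k_group, 15)
  expect_equal(res$k_complement, 4)
  expect_gt(res$h, 0)
  expect_equal(res$p_value, exact_binomial_test(15, 18, 0.5))
  # identical groups give zero effect size
  tab_eq <- make_table(list(
    list(subject = "S1", n_beats = 3, delta_s = 0.15, rho = 0.1,
         n_late = 9, n_early = 9),
    list(subject = "S1", n_beats = 3, delta_s = 1.2, rho = 0.1,
         n_late = 9, n_early = 9)))
  expect_equal(pooled_condition_test(tab_eq,
                                     function(d) d$delta_s > 0.5,
                                     outcome = "correct")$h, 0)
  expect_error(pooled_condition_test(tab, function(d) d$delta_s > 2),
               "empty")
})
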