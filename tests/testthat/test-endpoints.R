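test_that("square-root series sums lesion areas before taking the root", {
  v <- data.frame(visit_month = c(0, 6, 12),
                  hypertd_total_area_mm2 = c(0, 0.09, 0.04 + 0.05))
  s <- sqrt_area_series(v)
  expect_equal(s$y_mm, c(0, 0.3, 0.3))
  expect_equal(s$t_months, v$visit_month)
})

test_that("LSR slope matches closed-form anchors and handles degenerate input", {
  flat <- data.frame(t_months = c(0, 12, 24), y_mm = 0)
  est <- lsr_slope(flat)
  expect_identical(est$slope_mm_per_year, 0)
  expect_true(est$is_zero)

  line <- data.frame(t_months = c(0, 12, 24), y_mm = c(0, 0.1, 0.2))
  expect_equal(lsr_slope(line)$slope_mm_per_year, 0.1, tolerance = 1e-12)

  # normal-equations value frozen from the closed form 12 * 5.145 / 309
  mixed <- data.frame(t_months = c(0, 5, 14, 23), y_mm = c(0, 0, 0.22, 0.35))
  expect_equal(lsr_slope(mixed)$slope_mm_per_year, 12 * 5.145 / 309,
               tolerance = 1e-12)
  expect_equal(lsr_slope(mixed)$slope_mm_per_year, 0.1998, tolerance = 1e-4)

  expect_error(lsr_slope(data.frame(t_months = 0, y_mm = 0)), "2 visits")
  expect_error(lsr_slope(data.frame(t_months = c(3, 3), y_mm = c(0, 1))),
               "time spread")
})

test_that("LSR slope agrees with the regression oracle on random series", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    t <- sort(runif(n, 0, 40)); y <- pmax(0, 0.2 * t / 12 + rnorm(n, 0, 0.1))
    if (all(y == 0)) y[n] <- 0.1
    series <- data.frame(t_months = t, y_mm = y)
    ours <- lsr_slope(series)$slope_mm_per_year
    oracle <- 12 * unname(coef(lm(y ~ t))[2])
    expect_equal(ours, oracle, tolerance = 1e-10)
    # invariances: intercept absorption and linear scaling
    shifted <- data.frame(t_months = t, y_mm = y + 0.7)
    expect_equal(lsr_slope(shifted)$slope_mm_per_year, ours, tolerance = 1e-9)
    scaled <- data.frame(t_months = t, y_mm = 3 * y)
    expect_equal(lsr_slope(scaled)$slope_mm_per_year, 3 * ours, tolerance = 1e-9)
  }
})

test_that("slope summaries use sample SD, interpolated percentiles and the zero share", {
  sl <- data.frame(eye_id = letters[1:4], slope_mm_per_year = c(0, 0, 0.1, 0.3),
                   intercept_mm = 0, n_visits = 3,
                   is_zero = c(TRUE, TRUE, FALSE, FALSE))
  s <- summarize_slopes(sl)
  expect_equal(s$mean, 0.1)
  expect_equal(s$zero_fraction, 0.5)
  expect_equal(s$sd, sd(c(0, 0, 0.1, 0.3)))
  expect_equal(s$median, unname(quantile(c(0, 0, 0.1, 0.3), 0.5)))

  same <- sl; same$slope_mm_per_year <- 0.2; same$is_zero <- FALSE
  expect_equal(summarize_slopes(same)$sd, 0)
  expect_error(summarize_slopes(sl[0, ]), "at least 2")
})

test_that("cumulative incidence reproduces the raw-proportion arithmetic", {
  expect_equal(round(100 * 15 / 76, 1), 19.7)
  expect_equal(round(100 * 32 / 79, 1), 40.5)
  scr <- screen_cohort(make_two_eye_cohort(), eligibility_profile("dv_hrf"))
  expect_equal(cumulative_incidence(scr, 12)$proportion, 0)    # onset at 14
  expect_equal(cumulative_incidence(scr, 24)$proportion, 0.5)  # 1 of 2 eyes
  expect_equal(cumulative_incidence(scr, 24)$n_events, 1L)
  # non-decreasing in horizon
  cfg <- design_config("dv_hrf", n_eyes = 150, seed = 12)
  scr <- screen_cohort(simulate_cohort(cfg), eligibility_profile("dv_hrf"))
  inc <- sapply(c(6, 12, 18, 24, 36), function(h)
    cumulative_incidence(scr, h)$proportion)
  expect_true(all(diff(inc) >= 0))
})

test_that("onset medians: among developers vs survival-curve reading", {
  scr <- screen_cohort(make_two_eye_cohort(), eligibility_profile("dv_hrf"))
  om <- onset_median(scr, n_boot = 200, seed = 2)
  expect_equal(om$median_months, 14)    # single developer
  expect_equal(om$n_developers, 1L)
  expect_equal(unname(om$ci), c(14, 14))

  # when fewer than half the eyes progress, the survival median is undefined
  # while the among-developers median is finite
  cfg <- design_config("dv_hrf", n_eyes = 400, seed = 8)
  scr <- screen_cohort(simulate_cohort(cfg), eligibility_profile("dv_hrf"))
  inc24 <- cumulative_incidence(scr, 24)$proportion
  om <- onset_median(scr, n_boot = 200, seed = 2)
  expect_lt(inc24, 0.5)
  expect_true(is.finite(om$median_months))
  expect_true(is.na(om$survival_median_months) ||
              om$survival_median_months > om$median_months)
})

test_that("mixed-effects fit recovers known Gaussian slope parameters", {
  set.seed(41)
  n_eyes <- 500
  rows <- lapply(seq_len(n_eyes), function(i) {
    slope <- rnorm(1, 0.15, 0.18); int <- rnorm(1, 2.0, 0.05)
    t <- seq(0, 36, by = 4) + runif(10, 0, 2)
    data.frame(eye_id = sprintf("e%04d", i), patient_id = sprintf("e%04d", i),
               visit_month = t, dv_mm3 = 0.3, hrf_area_mm2 = 0.1,
               hypertd_total_area_mm2 =
                 (int + slope * t / 12 + rnorm(10, 0, 0.02))^2,
               max_gld_um = 300, exudation = FALSE)
  })
  co <- hypertd_cohort(do.call(rbind, rows))
  fit <- fit_lmm(co)
  expect_lt(abs(fit$mean_slope_mm_per_year - 0.15), 0.01)
  expect_lt(abs(fit$between_subject_sd - 0.18), 0.03)

  # degenerate: identical slopes give (near) zero between-subject SD
  rows0 <- lapply(seq_len(12), function(i) {
    t <- seq(0, 24, by = 3)
    data.frame(eye_id = sprintf("z%02d", i), patient_id = sprintf("z%02d", i),
               visit_month = t, dv_mm3 = 0.3, hrf_area_mm2 = 0.1,
               hypertd_total_area_mm2 = (0.3 + 0.1 * t / 12)^2,
               max_gld_um = 300, exudation = FALSE)
  })
  fit0 <- fit_lmm(hypertd_cohort(do.call(rbind, rows0)))
  expect_lt(fit0$between_subject_sd, 1e-4)

  expect_error(fit_lmm(make_two_eye_cohort()), "at least 10")
})

test_that("the mixed model smooths away the zero spike on simulated cohorts", {
  cfg <- design_config("dv_hrf", n_eyes = 300, seed = 23)
  fit <- hypertd_slopes(simulate_cohort(cfg), "dv_hrf")
  expect_gt(fit$summary$zero_fraction, 0.3)
  lmm <- fit_lmm(fit$screen)
  expect_gt(lmm$mean_slope_mm_per_year, 0)
  expect_equal(lmm$mean_slope_mm_per_year, fit$summary$mean, tolerance = 0.05)
})
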