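test_that("required sample sizes match the noncentral-t oracle and the floor", {
  # independent oracle: stats::power.t.test
  cases <- list(c(0.0375, 0.18, 0.10), c(0.0750, 0.20, 0.10),
                c(0.0400, 0.16, 0.15), c(0.0800, 0.18, 0.10),
                c(0.0675, 0.23, 0.05))
  for (cs in cases) {
    ours <- required_n_per_arm(cs[1], cs[2], cs[3])$n_per_arm
    n_star <- stats::power.t.test(delta = cs[1], sd = cs[2],
                                  sig.level = cs[3], power = 0.80,
                                  strict = TRUE)$n
    cand <- max(2, floor(n_star) - 1):(ceiling(n_star) + 1)
    pow <- sapply(cand, function(k)
      stats::power.t.test(n = k, delta = cs[1], sd = cs[2],
                          sig.level = cs[3], strict = TRUE)$power)
    oracle <- cand[which(pow >= 0.80)[1]]
    expect_equal(ours, oracle)
  }
  # df floor: a huge effect still needs 2 per arm
  expect_identical(required_n_per_arm(10, 0.1, 0.05)$n_per_arm, 2L)
})

test_that("power_at_n is exact, minimal at the required n, and equals alpha at no effect", {
  res <- required_n_per_arm(0.0375, 0.18, 0.10)
  expect_gte(power_at_n(res$n_per_arm, 0.0375, 0.18, 0.10), 0.80)
  expect_lt(power_at_n(res$n_per_arm - 1, 0.0375, 0.18, 0.10), 0.80)
  expect_gte(res$achieved_power, 0.80)
  expect_lt(res$achieved_power, 0.81)
  expect_equal(power_at_n(50, 0, 0.18, 0.10), 0.10, tolerance = 1e-10)
  # strictly monotone in n, delta, and (inversely) sd
  expect_gt(power_at_n(90, 0.075, 0.188, 0.1), power_at_n(89, 0.075, 0.188, 0.1))
  expect_gt(power_at_n(89, 0.076, 0.188, 0.1), power_at_n(89, 0.075, 0.188, 0.1))
  expect_lt(power_at_n(89, 0.075, 0.190, 0.1), power_at_n(89, 0.075, 0.188, 0.1))
})

test_that("attrition inflation rounds totals up to even after dividing by 0.9", {
  expect_identical(inflate_total(572), 636L)
  expect_identical(inflate_total(178), 198L)
  expect_identical(inflate_total(0), 0L)
  expect_error(inflate_total(571), "even")
})

test_that("critical difference collapses to delta at 50% power", {
  res <- required_n_per_arm(0.06, 0.19, 0.10, power = 0.50)
  expect_lt(abs(critical_difference(res$n_per_arm, 0.19, 0.10) - 0.06), 0.002)
})

test_that("required n is monotone across the full design grids", {
  for (d in c("dv_hrf", "hrf_only")) {
    tab <- build_design_table(effect_grid(d))
    # non-increasing in delta within (alpha, sd)
    for (a in unique(tab$alpha)) for (s in unique(tab$sd)) {
      sub <- tab[tab$alpha == a & tab$sd == s, ]
      sub <- sub[order(sub$delta), ]
      expect_true(all(diff(sub$n_per_arm) <= 0))
    }
    # non-decreasing in sd within (alpha, delta)
    for (a in unique(tab$alpha)) for (dd in unique(tab$delta)) {
      sub <- tab[tab$alpha == a & tab$delta == dd, ]
      sub <- sub[order(sub$sd), ]
      expect_true(all(diff(sub$n_per_arm) >= 0))
    }
    # non-increasing in alpha within (sd, delta)
    for (s in unique(tab$sd)) for (dd in unique(tab$delta)) {
      sub <- tab[tab$sd == s & tab$delta == dd, ]
      sub <- sub[order(sub$alpha, decreasing = TRUE), ]
      expect_true(all(diff(sub$n_per_arm) >= 0))
    }
    # normal approximation is within 2 of the exact answer everywhere
    z <- qnorm(1 - tab$alpha / 2) + qnorm(0.80)
    n_norm <- 2 * (tab$sd / tab$delta)^2 * z^2
    expect_true(all(abs(tab$n_per_arm - n_norm) <= 2))
    expect_true(all(tab$n_total_inflated >= tab$n_total))
  }
})

test_that("design tables format cells as printed", {
  tab1 <- build_design_table(effect_grid("dv_hrf"))
  cell <- tab1[tab1$alpha == 0.10 & tab1$sd == 0.18 & tab1$reduction_pct == 50, ]
  expect_equal(cell$cell, "144 (72:72)")
  cell25 <- tab1[tab1$alpha == 0.10 & tab1$sd == 0.18 & tab1$reduction_pct == 25, ]
  expect_equal(cell25$cell, "572 (286:286)")
  expect_equal(cell25$cell_inflated, "636 (318:318)")

  tab2 <- build_design_table(effect_grid("hrf_only"))
  c2 <- tab2[tab2$alpha == 0.05 & tab2$sd == 0.18 & tab2$reduction_pct == 25, ]
  expect_equal(c2$n_total, 638L)

  single <- effect_grid("dv_hrf")
  single$alpha_list <- 0.10; single$sd_list <- 0.18
  single$deltas <- 0.0750; single$reductions <- 50
  expect_equal(nrow(build_design_table(single)), 1L)
})

test_that("simulated power has the right size and agrees with the analytic value", {
  # size: no effect, Gaussian slopes
  s0 <- simulate_power(list(mean = 0.153, sd = 0.188), 0, 89, 0.10,
                       reps = 2000, seed = 5)
  expect_lt(abs(s0$power - 0.10), 3 * sqrt(0.10 * 0.90 / 2000))

  # mean-shift effect preserves the common SD of the analytic framing
  s1 <- simulate_power(list(mean = 0.153, sd = 0.188), 0.5, 89, 0.10,
                       reps = 2000, seed = 6, effect_type = "shift")
  analytic <- power_at_n(89, 0.5 * 0.153, 0.188, 0.10)
  expect_lt(abs(s1$power - analytic), 3 * s1$mc_se)

  # multiplicative effects also shrink the treated arm's spread, so power
  # can only be higher than the equal-SD analytic value
  s2 <- simulate_power(list(mean = 0.153, sd = 0.188), 0.5, 89, 0.10,
                       reps = 2000, seed = 6)
  expect_gt(s2$power, analytic - 3 * s2$mc_se)

  # empirical zero-inflated pool: t test is robust to the non-normal shape
  cfg <- design_config("dv_hrf", n_eyes = 600, seed = 14)
  pool <- hypertd_slopes(simulate_cohort(cfg), "dv_hrf")$slopes$slope_mm_per_year
  target_delta <- 0.5 * mean(pool)
  se <- simulate_power(pool, 0.5, 89, 0.10, reps = 2000, seed = 7,
                       effect_type = "shift")
  analytic_emp <- power_at_n(89, target_delta, sd(pool), 0.10)
  expect_lt(abs(se$power - analytic_emp), 0.05)

  expect_error(simulate_power(numeric(0), 0.5, 89, 0.10), "empty")
})
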