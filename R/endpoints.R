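# Progression estimands: square-root hyperTD area series, per-eye
# zero-inflated least-squares slopes, empirical summaries, fixed-horizon
# incidence, onset medians, and the mixed-effects sensitivity fit.

#' Square-root total hyperTD area series for one eye
#'
#' The endpoint series is the square root of the summed area of all large
#' hyperTDs at each visit, regardless of the number of lesions (areas are
#' summed before taking the root). Zero-area visits are preserved: they
#' carry the information that the eye had not (yet) progressed.
#'
#' @param course one eye's re-based visits (first visit at t = 0).
#' @return Data frame with `t_months` and `y_mm`.
#' @export
sqrt_area_series <- function(course) {
  data.frame(t_months = course$visit_month,
             y_mm = sqrt(course$hypertd_total_area_mm2))
}

#' Per-eye least-squares slope of the square-root area series
#'
#' Ordinary least squares through all visits from the analytic baseline to
#' the last follow-up, zeros included; eyes that never show a lesion get a
#' slope of exactly 0 (`is_zero = TRUE`), preserving the point mass at zero
#' in the population slope distribution. The slope is fitted per month and
#' reported in mm/year.
#'
#' @param series a [sqrt_area_series()] data frame (or anything with
#'   `t_months` and `y_mm`).
#' @return List with `slope_mm_per_year`, `intercept_mm`, `n_visits`,
#'   `is_zero`.
#' @export
lsr_slope <- function(series) {
  t <- series$t_months; y <- series$y_mm
  if (length(t) < 2) stop("LSR slope needs at least 2 visits")
  if (max(t) == min(t)) stop("LSR slope needs time spread between visits")
  if (all(y == 0)) {
    return(list(slope_mm_per_year = 0, intercept_mm = 0,
                n_visits = length(t), is_zero = TRUE))
  }
  tc <- t - mean(t)
  b <- sum(tc * (y - mean(y))) / sum(tc^2)       # per month
  list(slope_mm_per_year = 12 * b,
       intercept_mm = mean(y) - b * mean(t),
       n_visits = length(t), is_zero = FALSE)
}

#' Per-eye slopes for a screened cohort
#'
#' @param screened a `hypertd_screen` (from [screen_cohort()]) or a re-based
#'   `hypertd_cohort`.
#' @return Data frame with one row per eligible eye: `eye_id`,
#'   `slope_mm_per_year`, `intercept_mm`, `n_visits`, `is_zero`.
#' @export
cohort_slopes <- function(screened) {
  cohort <- if (inherits(screened, "hypertd_screen")) screened$cohort else screened
  eyes <- split(as.data.frame(cohort), cohort$eye_id)
  if (!length(eyes))
    return(data.frame(eye_id = character(), slope_mm_per_year = numeric(),
                      intercept_mm = numeric(), n_visits = integer(),
                      is_zero = logical()))
  rows <- lapply(eyes, function(v) {
    est <- lsr_slope(sqrt_area_series(v))
    data.frame(eye_id = v$eye_id[1], slope_mm_per_year = est$slope_mm_per_year,
               intercept_mm = est$intercept_mm, n_visits = est$n_visits,
               is_zero = est$is_zero, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Empirical summary of a zero-inflated slope distribution
#'
#' Mean, sample SD (n-1 denominator), and percentiles by linear
#' interpolation between order statistics; `zero_fraction` is the share of
#' eyes whose series never left zero.
#'
#' @param slopes data frame from [cohort_slopes()].
#' @return A `slope_summary` list: `n`, `mean`, `sd`, `p10`, `median`,
#'   `p90`, `zero_fraction`.
#' @export
summarize_slopes <- function(slopes) {
  if (nrow(slopes) < 2) stop("slope summary needs at least 2 eyes")
  s <- slopes$slope_mm_per_year
  q <- stats::quantile(s, c(0.10, 0.50, 0.90), type = 7, names = FALSE)
  structure(list(n = length(s), mean = mean(s), sd = stats::sd(s),
                 p10 = q[1], median = q[2], p90 = q[3],
                 zero_fraction = mean(slopes$is_zero)),
            class = "slope_summary")
}

#' @export
print.slope_summary <- function(x, ...) {
  cat(sprintf("Zero-inflated LSR slope distribution (n = %d eyes)\n", x$n))
  cat(sprintf("  mean %.4f  sd %.4f  mm/year\n", x$mean, x$sd))
  cat(sprintf("  P10 %.4f  median %.4f  P90 %.4f\n", x$p10, x$median, x$p90))
  cat(sprintf("  zero-slope fraction %.3f\n", x$zero_fraction))
  invisible(x)
}

#' Observed onset time of the first large hyperTD per eligible eye
#'
#' Onset is the time of the first visit at which a large hyperTD is present
#' (interval censoring between visits is ignored, matching a visit-based
#' grading workflow). `NA` for eyes that never develop one.
#'
#' @param screened a `hypertd_screen`.
#' @return Data frame with `eye_id`, `onset_month` (NA = none),
#'   `last_month`.
#' @export
onset_times <- function(screened) {
  cohort <- screened$cohort
  eyes <- split(as.data.frame(cohort), cohort$eye_id)
  if (!length(eyes))
    return(data.frame(eye_id = character(), onset_month = numeric(),
                      last_month = numeric()))
  rows <- lapply(eyes, function(v) {
    idx <- which(is_large_hypertd(v$max_gld_um))
    data.frame(eye_id = v$eye_id[1],
               onset_month = if (length(idx)) v$visit_month[idx[1]] else NA_real_,
               last_month = max(v$visit_month), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Fixed-horizon cumulative incidence of large hyperTDs
#'
#' Raw proportion: eyes whose first large hyperTD is observed at or before
#' the horizon, over all eligible eyes (not a risk-set estimator).
#'
#' @param screened a `hypertd_screen`.
#' @param horizon_months horizon after the analytic baseline, months.
#' @return List with `proportion`, `n_events`, `n_total`.
#' @export
cumulative_incidence <- function(screened, horizon_months) {
  stopifnot(horizon_months > 0)
  ot <- onset_times(screened)
  n_events <- sum(!is.na(ot$onset_month) & ot$onset_month <= horizon_months)
  list(proportion = if (nrow(ot)) n_events / nrow(ot) else 0,
       n_events = n_events, n_total = nrow(ot))
}

#' Median time to large hyperTD onset among developers
#'
#' The median of observed onset times among eyes that developed a large
#' hyperTD, with a seeded percentile-bootstrap confidence interval over
#' eyes. A Kaplan-Meier survival median (treating non-developers as
#' censored at their last visit) is also reported for transparency: when
#' fewer than half the eyes progress the survival median is undefined,
#' whereas the among-developers median is always available.
#'
#' @param screened a `hypertd_screen`.
#' @param conf_level confidence level for the bootstrap interval.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return List with `median_months`, `ci`, `survival_median_months`,
#'   `n_developers`.
#' @export
onset_median <- function(screened, conf_level = 0.95, n_boot = 2000, seed = 1) {
  ot <- onset_times(screened)
  dev <- ot$onset_month[!is.na(ot$onset_month)]
  if (!length(dev)) stop("no eyes developed a large hyperTD")
  med <- stats::median(dev)
  set.seed(seed)
  boots <- replicate(n_boot,
    stats::median(dev[sample.int(length(dev), replace = TRUE)]))
  alpha <- 1 - conf_level
  ci <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  fit <- survival::survfit(
    survival::Surv(ifelse(is.na(ot$onset_month), ot$last_month, ot$onset_month),
                   !is.na(ot$onset_month)) ~ 1)
  surv_med <- unname(summary(fit)$table["median"])
  list(median_months = med, ci = ci, survival_median_months = surv_med,
       n_developers = length(dev))
}

#' Linear mixed-effects sensitivity fit of square-root area growth
#'
#' Random-intercept, random-slope model of square-root total hyperTD area
#' against time across eyes, fitted with `lme4::lmer`. This accommodates
#' irregular follow-up but assumes Gaussian subject-level slopes, so it
#' does not preserve the point mass at zero; it is a sensitivity analysis,
#' not the primary estimand.
#'
#' @param screened a `hypertd_screen` or re-based `hypertd_cohort` with at
#'   least 10 eyes, each with at least 2 visits.
#' @return An `lmm_fit` list: `mean_slope_mm_per_year`,
#'   `between_subject_sd`, `mean_intercept_mm`, `converged`, `messages`,
#'   and the underlying `model`.
#' @export
fit_lmm <- function(screened) {
  cohort <- if (inherits(screened, "hypertd_screen")) screened$cohort else screened
  d <- data.frame(eye = cohort$eye_id, t_years = cohort$visit_month / 12,
                  y = sqrt(cohort$hypertd_total_area_mm2))
  n_eyes <- length(unique(d$eye))
  if (n_eyes < 10) stop("mixed-effects fit needs at least 10 eyes")
  if (any(table(d$eye) < 2)) stop("every eye needs at least 2 visits")
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(y ~ t_years + (t_years | eye), data = d,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  vc <- as.data.frame(lme4::VarCorr(fit))
  slope_sd <- vc$sdcor[vc$grp == "eye" & vc$var1 == "t_years" & is.na(vc$var2)]
  structure(list(mean_slope_mm_per_year = unname(lme4::fixef(fit)["t_years"]),
                 between_subject_sd = slope_sd,
                 mean_intercept_mm = unname(lme4::fixef(fit)["(Intercept)"]),
                 converged = length(msgs) == 0, messages = msgs, model = fit),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Mixed-effects sensitivity fit (random intercept + slope)\n")
  cat(sprintf("  mean slope %.4f mm/year, between-subject SD %.4f\n",
              x$mean_slope_mm_per_year, x$between_subject_sd))
  if (!x$converged) cat("  convergence messages:", x$messages, "\n")
  invisible(x)
}
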