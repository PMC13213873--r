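# Central fit: screen a cohort against an eligibility profile and estimate
# the zero-inflated distribution of per-eye LSR slopes.

#' Fit the zero-inflated slope model to a natural-history cohort
#'
#' The one-stop analysis: screens every eye against the eligibility
#' profile, re-bases eligible eyes to their analytic baseline, computes the
#' per-eye least-squares slope of square-root total hyperTD area (zeros
#' included), and summarizes the resulting zero-inflated slope
#' distribution.
#'
#' @param cohort a [hypertd_cohort()].
#' @param profile an [eligibility_profile()], or a design name
#'   (`"dv_hrf"` / `"hrf_only"`).
#' @return A `hypertd_slopes` object with components `screen`
#'   (the `hypertd_screen`), `slopes` (per-eye estimates), `summary`
#'   (a `slope_summary`) and `profile`. Methods: `print`, `summary`,
#'   `coef` (named per-eye slope vector), `plot`.
#' @export
hypertd_slopes <- function(cohort, profile = "dv_hrf") {
  if (is.character(profile)) profile <- eligibility_profile(profile)
  scr <- screen_cohort(cohort, profile)
  slopes <- cohort_slopes(scr)
  smry <- if (nrow(slopes) >= 2) summarize_slopes(slopes) else NULL
  structure(list(screen = scr, slopes = slopes, summary = smry,
                 profile = profile),
            class = "hypertd_slopes")
}

#' @export
print.hypertd_slopes <- function(x, ...) {
  cat("hyperTD progression slope fit (design ", x$profile$design, ")\n",
      sep = "")
  cat("  eligible eyes:", nrow(x$slopes), "of", nrow(x$screen$results), "\n")
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' @export
summary.hypertd_slopes <- function(object, ...) {
  list(screen_tally = object$screen$tally, slope_summary = object$summary)
}

#' @export
coef.hypertd_slopes <- function(object, ...) {
  stats::setNames(object$slopes$slope_mm_per_year, object$slopes$eye_id)
}

#' @export
plot.hypertd_slopes <- function(x, max_eyes = 60, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  cohort <- x$screen$cohort
  ids <- unique(cohort$eye_id)
  ids <- ids[seq_len(min(length(ids), max_eyes))]
  sub <- cohort[cohort$eye_id %in% ids, ]
  graphics::plot(NA, xlim = range(sub$visit_month),
                 ylim = c(0, max(sqrt(sub$hypertd_total_area_mm2), 0.1)),
                 xlab = "months from analytic baseline",
                 ylab = expression(sqrt("total hyperTD area") ~ "(mm)"),
                 main = "Square-root area trajectories")
  for (id in ids) {
    v <- sub[sub$eye_id == id, ]
    graphics::lines(v$visit_month, sqrt(v$hypertd_total_area_mm2),
                    col = grDevices::grey(0.4, 0.5))
  }
  graphics::hist(x$slopes$slope_mm_per_year, breaks = 30,
                 xlab = "LSR slope (mm/year)",
                 main = "Zero-inflated slope distribution")
  invisible(x)
}
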