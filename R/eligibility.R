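# Eligibility screening: the two OCT-biomarker inclusion profiles and the
# analytic-baseline rule turning a natural-history eye into a trial record.

#' Is a lesion a large hyperTD?
#'
#' A hypertransmission defect counts as "large" when its greatest linear
#' dimension is at least 250 micrometers (inclusive).
#'
#' @param gld_um greatest linear dimension(s), micrometers, finite and >= 0.
#' @return Logical vector.
#' @export
is_large_hypertd <- function(gld_um) {
  if (any(!is.finite(gld_um)) || any(gld_um < 0))
    stop("gld_um must be finite and non-negative")
  gld_um >= 250
}

#' Filter HRF candidate regions by the minimum measurable area
#'
#' Regions smaller than 1440 square micrometers (10 pixels on a 6x6 mm
#' raster) are below the reproducibly measurable floor and are dropped;
#' order is preserved.
#'
#' @param region_areas_um2 numeric vector of candidate region areas, um^2.
#' @return The retained areas, in input order.
#' @export
min_hrf_region_filter <- function(region_areas_um2) {
  stopifnot(all(region_areas_um2 >= 0))
  region_areas_um2[region_areas_um2 >= 1440]
}

#' Build a trial-design eligibility profile
#'
#' Design `"dv_hrf"`: drusen volume >= 0.20 mm^3 and any detectable HRF
#' (area strictly > 0 after the region floor). Design `"hrf_only"`: HRF
#' area >= 0.07 mm^2 regardless of drusen volume. Both require no large
#' hyperTD at the qualifying visit and at least `min_followup_months` of
#' subsequent follow-up.
#'
#' @param design `"dv_hrf"` or `"hrf_only"`.
#' @param dv_min_mm3 drusen-volume threshold (ignored for `"hrf_only"`).
#' @param hrf_min_mm2 HRF-area threshold; exclusive for `"dv_hrf"`
#'   (any detectable HRF), inclusive for `"hrf_only"`.
#' @param min_followup_months required follow-up after the analytic baseline.
#' @param require_no_large_hypertd exclude eyes with a large hyperTD before
#'   qualification.
#' @return An `eligibility_profile` list.
#' @export
eligibility_profile <- function(design = c("dv_hrf", "hrf_only"),
                                dv_min_mm3 = if (design == "dv_hrf") 0.20 else 0,
                                hrf_min_mm2 = if (design == "dv_hrf") 0 else 0.07,
                                min_followup_months = 12,
                                require_no_large_hypertd = TRUE) {
  design <- match.arg(design)
  stopifnot(dv_min_mm3 >= 0, hrf_min_mm2 >= 0, min_followup_months > 0)
  structure(list(design = design, dv_min_mm3 = dv_min_mm3,
                 hrf_min_mm2 = hrf_min_mm2,
                 min_followup_months = min_followup_months,
                 require_no_large_hypertd = require_no_large_hypertd),
            class = "eligibility_profile")
}

meets_biomarkers <- function(profile, dv, hrf) {
  hrf_ok <- if (profile$design == "dv_hrf") hrf > profile$hrf_min_mm2
            else hrf >= profile$hrf_min_mm2
  dv_ok <- if (profile$design == "dv_hrf") dv >= profile$dv_min_mm3 else TRUE
  dv_ok & hrf_ok
}

#' Screen one eye against an eligibility profile
#'
#' Scans visits in time order for the analytic baseline: the first visit
#' meeting the profile's biomarker thresholds with no large hyperTD present
#' and no prior exudation. An eye whose first large hyperTD (or exudation)
#' precedes any qualifying visit is excluded. Eligibility additionally
#' requires `min_followup_months` between the analytic baseline and the
#' last usable (pre-exudation) visit. Ineligibility is a value, never an
#' error.
#'
#' @param course data frame of one eye's visits (cohort rows), time-ordered.
#' @param profile an [eligibility_profile()].
#' @return List with `eye_id`, `eligible`, `baseline_index` (or `NA`),
#'   `exclusion_reason` (`""` when eligible), `baseline_month`,
#'   `last_usable_index`.
#' @export
screen_eye <- function(course, profile) {
  stopifnot(nrow(course) >= 1)
  res <- list(eye_id = course$eye_id[1], eligible = FALSE,
              baseline_index = NA_integer_, exclusion_reason = "",
              baseline_month = NA_real_, last_usable_index = NA_integer_)
  baseline <- NA_integer_
  for (i in seq_len(nrow(course))) {
    if (isTRUE(course$exudation[i])) {
      res$exclusion_reason <- "exudation_before_qualifying"
      return(res)
    }
    if (profile$require_no_large_hypertd &&
        is_large_hypertd(course$max_gld_um[i])) {
      res$exclusion_reason <- "baseline_hypertd"
      return(res)
    }
    if (meets_biomarkers(profile, course$dv_mm3[i], course$hrf_area_mm2[i])) {
      baseline <- i
      break
    }
  }
  if (is.na(baseline)) {
    res$exclusion_reason <- "never_qualified"
    return(res)
  }
  usable <- which(!course$exudation)        # exudation censors follow-up
  usable <- usable[usable >= baseline]
  last_usable <- max(usable)
  followup <- course$visit_month[last_usable] - course$visit_month[baseline]
  res$baseline_index <- baseline
  res$baseline_month <- course$visit_month[baseline]
  res$last_usable_index <- last_usable
  if (followup < profile$min_followup_months) {
    res$exclusion_reason <- "insufficient_followup"
  } else {
    res$eligible <- TRUE
  }
  res
}

#' Screen a cohort and re-base eligible eyes to their analytic baseline
#'
#' Applies [screen_eye()] to every eye, then returns the eligible eyes with
#' time re-origined so the analytic baseline is t = 0 and follow-up censored
#' at the last pre-exudation visit, plus a per-eye screening table and an
#' exclusion tally.
#'
#' @param cohort a [hypertd_cohort()].
#' @param profile an [eligibility_profile()].
#' @return A `hypertd_screen` list: `results` (one row per eye), `cohort`
#'   (re-based eligible visits), `tally` (named exclusion counts), `profile`.
#' @export
screen_cohort <- function(cohort, profile) {
  stopifnot(inherits(cohort, "hypertd_cohort"))
  eyes <- split(as.data.frame(cohort), cohort$eye_id)
  scr <- lapply(eyes, screen_eye, profile = profile)
  results <- data.frame(
    eye_id = vapply(scr, `[[`, "", "eye_id"),
    eligible = vapply(scr, `[[`, NA, "eligible"),
    baseline_index = vapply(scr, `[[`, NA_integer_, "baseline_index"),
    exclusion_reason = vapply(scr, `[[`, "", "exclusion_reason"),
    stringsAsFactors = FALSE, row.names = NULL)
  rebased <- lapply(scr[results$eligible], function(s) {
    v <- eyes[[s$eye_id]][s$baseline_index:s$last_usable_index, , drop = FALSE]
    v <- v[!v$exudation, , drop = FALSE]
    v$visit_month <- v$visit_month - v$visit_month[1]
    v
  })
  reasons <- c("never_qualified", "baseline_hypertd", "insufficient_followup",
               "exudation_before_qualifying")
  tally <- vapply(reasons, function(r) sum(results$exclusion_reason == r), 0L)
  tally <- c(eligible = sum(results$eligible), tally)
  rebased_df <- if (length(rebased)) do.call(rbind, rebased)
                else as.data.frame(cohort)[0, ]
  out_cohort <- hypertd_cohort(rebased_df,
                               provenance = paste0(attr(cohort, "provenance"),
                                                   " | screened:", profile$design))
  structure(list(results = results, cohort = out_cohort, tally = tally,
                 profile = profile),
            class = "hypertd_screen")
}

#' @export
print.hypertd_screen <- function(x, ...) {
  cat("Eligibility screen (design ", x$profile$design, ")\n", sep = "")
  cat("  eyes screened: ", nrow(x$results), "\n", sep = "")
  for (nm in names(x$tally)) cat(sprintf("  %-28s %d\n", nm, x$tally[[nm]]))
  invisible(x)
}
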