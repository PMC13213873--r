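#' @keywords internal
"_PACKAGE"

# Column schema for the longitudinal interchange format. One row per visit.
COHORT_COLUMNS <- c("eye_id", "patient_id", "visit_month", "dv_mm3",
                    "hrf_area_mm2", "hypertd_total_area_mm2", "max_gld_um",
                    "exudation")
COHORT_NUMERIC <- c("visit_month", "dv_mm3", "hrf_area_mm2",
                    "hypertd_total_area_mm2", "max_gld_um")

#' Construct a longitudinal eye-level cohort table
#'
#' A cohort is a data frame with one row per OCT visit and a fixed column
#' schema: `eye_id`, `patient_id`, `visit_month` (elapsed months since the
#' eye's first record), `dv_mm3` (drusen volume in the 5-mm fovea-centered
#' circle), `hrf_area_mm2` (hyperreflective-foci area in the same circle),
#' `hypertd_total_area_mm2` (summed area of all large hypertransmission
#' defects), `max_gld_um` (greatest linear dimension of the largest lesion
#' candidate, micrometers), and a logical `exudation` flag. Rows are sorted
#' by `eye_id` then `visit_month`.
#'
#' @param visits data frame holding the columns above.
#' @param provenance free-text origin note (generator seed or file path).
#' @return A validated `hypertd_cohort` (a data frame).
#' @export
hypertd_cohort <- function(visits, provenance = "unspecified") {
  stopifnot(is.data.frame(visits))
  missing_cols <- setdiff(COHORT_COLUMNS, names(visits))
  extra_cols <- setdiff(names(visits), COHORT_COLUMNS)
  if (length(missing_cols) || length(extra_cols)) {
    stop("cohort schema error: missing [", paste(missing_cols, collapse = ", "),
         "], unknown [", paste(extra_cols, collapse = ", "), "]")
  }
  visits <- visits[, COHORT_COLUMNS]
  for (cn in COHORT_NUMERIC) visits[[cn]] <- as.numeric(visits[[cn]])
  visits$eye_id <- as.character(visits$eye_id)
  visits$patient_id <- as.character(visits$patient_id)
  visits$exudation <- as.logical(visits$exudation)
  visits <- visits[order(visits$eye_id, visits$visit_month), , drop = FALSE]
  rownames(visits) <- NULL
  validate_cohort(visits)
  structure(visits, provenance = provenance,
            class = c("hypertd_cohort", "data.frame"))
}

validate_cohort <- function(visits) {
  for (cn in COHORT_NUMERIC) {
    bad <- which(!is.finite(visits[[cn]]) | visits[[cn]] < 0)
    if (length(bad)) {
      stop("cohort validation error: ", cn, " negative or non-finite for eye ",
           visits$eye_id[bad[1]], " at row ", bad[1])
    }
  }
  if (anyNA(visits$exudation)) stop("cohort validation error: exudation must be TRUE/FALSE")
  bad <- which(visits$hypertd_total_area_mm2 > 0 & visits$max_gld_um <= 0)
  if (length(bad)) {
    stop("cohort validation error: positive hyperTD area with zero GLD for eye ",
         visits$eye_id[bad[1]], " at row ", bad[1])
  }
  # strictly increasing visit times within eye (rows already sorted)
  same_eye <- visits$eye_id[-1] == visits$eye_id[-nrow(visits)]
  if (nrow(visits) > 1) {
    dup <- which(same_eye & diff(visits$visit_month) <= 0)
    if (length(dup)) {
      stop("cohort validation error: duplicate or non-increasing visit_month for eye ",
           visits$eye_id[dup[1] + 1], " at row ", dup[1] + 1)
    }
  }
  invisible(visits)
}

#' Read a cohort from a delimited text file
#'
#' Expects the comma-separated interchange format written by
#' [write_cohort()]: header row with the documented columns, `"."` decimal
#' separator, UTF-8. Rows are grouped per eye and sorted by visit time;
#' schema and invariant violations raise errors naming the offending eye
#' and row.
#'
#' @param path file path.
#' @return A `hypertd_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  hypertd_cohort(raw, provenance = paste0("file:", path))
}

#' Write a cohort to a delimited text file
#'
#' Deterministic output: rows ordered by `eye_id` then `visit_month`, fixed
#' column order, numeric values rounded to 6 significant digits (well below
#' every decision threshold in the eligibility rules). [read_cohort()]
#' inverts it exactly for values representable at that precision, and
#' write-read-write is byte idempotent.
#'
#' @param cohort a `hypertd_cohort`.
#' @param path destination file path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "hypertd_cohort"))
  out <- as.data.frame(cohort)
  for (cn in COHORT_NUMERIC) out[[cn]] <- signif(out[[cn]], 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.hypertd_cohort <- function(x, ...) {
  n_eyes <- length(unique(x$eye_id))
  cat("hyperTD natural-history cohort: ", n_eyes, " eyes, ", nrow(x),
      " visits\n", sep = "")
  cat("provenance:", attr(x, "provenance"), "\n")
  NextMethod()
}
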