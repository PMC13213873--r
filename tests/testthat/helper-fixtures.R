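# Small deterministic fixtures built in code.

# A hand-written two-eye cohort: eye A develops a large hyperTD at month 14,
# eye B never does.
make_two_eye_cohort <- function() {
  hypertd_cohort(data.frame(
    eye_id = rep(c("A", "B"), each = 4),
    patient_id = rep(c("p1", "p2"), each = 4),
    visit_month = c(0, 5, 14, 23, 0, 4, 12, 20),
    dv_mm3 = c(0.25, 0.24, 0.23, 0.22, 0.30, 0.31, 0.29, 0.28),
    hrf_area_mm2 = c(0.05, 0.05, 0.04, 0.04, 0.10, 0.11, 0.10, 0.09),
    hypertd_total_area_mm2 = c(0, 0, 0.22^2, 0.35^2, 0, 0, 0, 0),
    max_gld_um = c(0, 0, 260, 400, 0, 0, 0, 0),
    exudation = FALSE), provenance = "fixture")
}

# Random valid cohorts for property-style tests, at 6-significant-digit
# precision so file round trips are exact.
make_random_cohort <- function(n_eyes, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n_eyes), function(i) {
    n <- sample(2:6, 1)
    t <- round(sort(c(0, cumsum(runif(n - 1, 1, 6)))), 2)
    onset <- sample(c(Inf, runif(1, 0, max(t))), 1)
    y <- ifelse(t >= onset, signif(0.22 + 0.1 * (t - onset) / 12, 6), 0)
    data.frame(eye_id = sprintf("e%03d", i), patient_id = sprintf("p%03d", i),
               visit_month = t,
               dv_mm3 = signif(runif(n, 0, 0.6), 6),
               hrf_area_mm2 = signif(runif(n, 0, 0.3), 6),
               hypertd_total_area_mm2 = signif(y^2, 6),
               max_gld_um = ifelse(y > 0, signif(2000 * y / sqrt(pi), 6), 0),
               exudation = FALSE)
  })
  hypertd_cohort(do.call(rbind, rows), provenance = "random-fixture")
}
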