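# Calibrated lognormal parameters of the per-eye post-onset growth rate
# (mm/year on the square-root area scale). Produced by
# scripts/calibrate_growth.R, which matches the screened cohort's
# zero-inflated LSR slope mean (0.153 / 0.161 mm/year) and 90th percentile
# (0.4026 / 0.3682 mm/year) on a large simulated cohort under each design's
# onset and follow-up models. Regenerate with:
#   Rscript scripts/calibrate_growth.R
GROWTH_CALIBRATION <- list(
  dv_hrf   = c(meanlog = -1.2744, sdlog = 0.7328),
  hrf_only = c(meanlog = -1.4120, sdlog = 0.7990)
)
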