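---
title: "Modeling iAMD trial designs with hyperTD growth endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling iAMD trial designs with hyperTD growth endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypertdtrial)
```

## The problem

Intermediate age-related macular degeneration (iAMD) precedes geographic
atrophy, and early-phase trials in this population need a structural
endpoint that responds within one to two years. Large choroidal
hypertransmission defects (hyperTDs) — en face OCT lesions with a greatest
linear dimension (GLD) of at least 250 µm, marking retinal pigment
epithelium attenuation — provide such an endpoint. Because eligible eyes
must be lesion-free at baseline, the endpoint has to integrate *lesion
onset* and *subsequent enlargement* into a single continuous quantity.

The estimand this package implements is the per-eye least-squares
regression (LSR) slope of the square root of the total large-hyperTD area
against time, in mm/year, computed over every visit from the analytic
baseline to the last follow-up *including visits with zero area*. Eyes
that never develop a lesion contribute a slope of exactly zero, so the
population slope distribution is zero-inflated: a point mass at zero plus
a right-skewed positive component. The square-root transform is the
standard device for making atrophy-like growth rates approximately
independent of baseline lesion size.

Two OCT-biomarker eligibility profiles define the enrolled populations:

* **dv_hrf** — drusen volume (DV) ≥ 0.20 mm³ within the 5-mm
  fovea-centered circle *and* any detectable hyperreflective-foci (HRF)
  area (> 0 mm² after the 1440 µm² minimum-region floor);
* **hrf_only** — HRF area ≥ 0.07 mm², regardless of DV.

In both profiles the analytic baseline is the *first* visit at which the
biomarker thresholds hold with no large hyperTD present and no prior
exudation, and at least 12 months of subsequent follow-up are required.
All thresholds are inclusive (≥) except the "any detectable HRF" rule,
which is strict. We implement the single-visit reading of qualification:
thresholds must hold at one visit, not persistently — the first such visit
becomes the time origin.

## The power engine

Sample sizes treat the per-eye annual slope as the analyzed quantity in a
two-arm, equal-allocation comparison with a two-sided pooled-variance
two-sample t test. For a true arm difference $\delta$ (mm/year), common
slope SD $\sigma$, and $n$ eyes per arm, the test statistic under the
alternative follows a noncentral t distribution with $2n-2$ degrees of
freedom and noncentrality $\delta\sqrt{n/2}/\sigma$; `power_at_n()`
evaluates the exact two-tailed rejection probability (both tails — the
"strict" convention, which is what reproduces the published grids at
permissive alphas such as 0.15), and `required_n_per_arm()` returns the
smallest integer $n$ reaching the target power. Supporting quantities:

* `critical_difference(n, sd, alpha)` = $t_{1-\alpha/2,\,2n-2}\,
  \sigma\sqrt{2/n}$, the smallest observed arm difference reaching
  significance;
* `inflate_total(n)` divides the total by 0.9 and rounds up to the next
  even integer — the attrition rule recovered from the published paired
  totals (572 → 636, 178 → 198; multiplying by 1.1 gives 630/196 and is
  wrong);
* `build_design_table(effect_grid(design))` crosses the tabulated effect
  sizes (25–50% reductions of the rounded control means 0.150/0.160, i.e.
  δ = 0.0375…0.0750 and 0.0400…0.0800 mm/year — the printed values, not
  recomputations from the unrounded means 0.153/0.161), the base and
  +10/20/30% SDs, and two-sided alphas 0.15/0.10/0.05.

`simulate_power()` estimates power by Monte Carlo from an arbitrary slope
source — a Gaussian specification or an empirical zero-inflated pool of
per-eye slopes. Two treatment-effect mechanisms are supported, and the
choice matters:

* `"multiplicative"` (default): every treatment draw is multiplied by
  $1-e$. A zero slope stays zero, preserving the zero spike, but the
  treatment arm's spread shrinks along with its mean, so simulated power
  *exceeds* the equal-SD analytic value.
* `"shift"`: treatment draws are reduced by $e \times$ the source mean.
  Both arms keep a common SD and the arm difference equals the analytic
  $\delta$, so with a Gaussian source the simulation converges to
  `power_at_n()` exactly; with an empirical zero-inflated pool it isolates
  the effect of non-normality on the t test (which is small at these
  sample sizes — the documented robustness check).

We default to the multiplicative mechanism because a proportional slowing
of progression cannot turn a non-developing eye into a negative slope; the
shift mechanism is the one to use when validating against the analytic
machinery.

## The natural-history generator

No patient-level data are distributed, so every downstream stage is
exercised against a synthetic cohort generator (`design_config()`,
`simulate_cohort()`) whose defaults encode the published cohort structure.

**Onset.** Time to the first large hyperTD is calibrated with
`calibrate_onset()` from the two fixed-horizon incidences by a two-point
fit on the complementary log-log survival scale. For the dv_hrf design
(19.7% at 12 months, 35.5% at 24) the implied Weibull shape is 0.999, so
the model collapses to an exponential with rate 0.01828/month fitted to
the 12-month point; for hrf_only (17.7%, 40.5%) the fit is a Weibull with
shape 1.414 and scale 38.15 months, passing through both points exactly.

**Growth.** At onset a lesion appears at the detection threshold: a
circular lesion with GLD 250 µm has square-root area
$a_0=\sqrt{\pi}\cdot0.125\approx0.2216$ mm. The observed series therefore
jumps from 0 to ≈ a₀, which is exactly why LSR slopes blend onset timing
with growth. After onset the latent square-root area grows linearly at a
per-eye rate $g$ (mm/year) drawn from a lognormal distribution. The
lognormal parameters are *calibrated*, not assumed: the cohort reports
slope summaries, not the latent growth distribution, so
`scripts/calibrate_growth.R` searches (meanlog, sdlog) until a large
simulated, screened cohort matches the published zero-inflated slope mean
(0.153 / 0.161 mm/year) and 90th percentile (0.4026 / 0.3682). The frozen
values are meanlog −1.274, sdlog 0.733 (dv_hrf) and meanlog −1.412, sdlog
0.799 (hrf_only). Measurement noise is additive on the square-root scale
(SD 0.02 mm, truncated at zero) and is applied only when a latent lesion
exists: pre-onset visits record exactly zero so the zero spike is exact,
and the lesion GLD is derived from the latent (noise-free) size so that a
lesion is "large" exactly when it exists.

**Schedule.** Visit gaps are gamma with mean 12/3.3 ≈ 3.6 months and SD
2.8 months, giving ≈ 3.3 ± 1.4 visits/year. Administrative follow-up is
lognormal with median 37.7 (dv_hrf) or 35.4 (hrf_only) months and sdlog
0.70 — the wide, right-skewed spread implied by the published follow-up
intervals — and the series always closes with an exit visit at the
censoring time itself, so the time of the last visit has exactly the
configured follow-up distribution and the observed zero-slope fraction
equals the latent fraction of eyes without onset before censoring.
Exudative AMD arrives as an exponential hazard calibrated to 11.1%
cumulative over the cohort's 59.1-month median follow-up; visits from the
detection visit onward are flagged/dropped, exudation before qualification
excludes the eye, and exudation after baseline censors follow-up at the
last clean visit.

**Biomarkers.** Baseline DV and HRF areas are lognormal (medians 0.35 mm³
and 0.10 mm², sdlog 0.45/0.70) with a mild downward drift (−3%/year),
matching the qualitative behavior of drusen and HRF as lesions emerge.
These trajectories only need to exercise the screening rules; they are a
generator convenience, not an estimand.

**Reproducibility.** Each eye consumes its own RNG substream derived from
(seed, eye index), so cohorts are byte-identical under a fixed
configuration and independent of generation order. Configurations
round-trip through JSON at full floating-point precision.

### What the generator does and does not emulate

Calibrated targets: the 12/24-month incidences, the zero-inflated slope
mean, and the slope P90 under each design's screening rules. Emergent but
close: the right-skew of the slope distribution, P10 = 0, and the
among-developer onset medians. Known departures: the published cohorts
show *more* developers over long follow-up (60.5%/67.1%) than any
constant- or Weibull-hazard model fitted to their own 12/24-month
incidences can produce at the published median follow-up — the real onset
hazard evidently accelerates beyond two years. The simulated zero-slope
fractions therefore sit near 0.48/0.39 rather than the published
0.39/0.33, and per-eye slope SDs run slightly above the published 0.188.
Passing calibration tests consequently shows that the pipeline recovers
the distributions the generator encodes, not that the generator is a
complete model of the disease.

## Numerical and design choices

* Percentiles use linear interpolation between order statistics
  (`quantile` type 7), the most common convention; the cohort source does
  not state one.
* Incidence denominators are all eligible eyes (raw proportions), matching
  the published 15/76 = 19.7% arithmetic, not risk-set estimators.
* Onset time is the first visit at which a large hyperTD is observed;
  interval censoring between visits is ignored, as in a visit-based
  grading workflow.
* The onset median is reported among developers (with a seeded
  2000-resample percentile-bootstrap CI); a Kaplan–Meier median is
  reported alongside because the two differ whenever fewer than half the
  eyes progress — the among-developers reading is the only one coherent
  with a 20.4-month median at 35.5% two-year incidence.
* The mixed-effects sensitivity fit (`fit_lmm`, via `lme4`) uses a random
  intercept and random slope per eye. It accommodates irregular visits but
  assumes Gaussian subject-level slopes and therefore reports no zero
  spike; it is deliberately secondary to the LSR estimand.
* An eye qualifying only at its final visit is ineligible (no follow-up
  remains); degenerate slope inputs (< 2 visits, zero time spread) and
  all-identical simulation pools raise explicit errors rather than NaNs.
* Problem sizes in the test suite: calibration checks run 5000-eye
  cohorts and 10⁵-draw onset simulations; Monte-Carlo power checks use
  2000–4000 replicates. These keep every stochastic check within three
  standard errors of its target while completing in seconds.

## A worked design calculation

```{r example, eval = FALSE}
library(hypertdtrial)

# exact sample size for a 50% slowing at the dv_hrf design's upper SD
required_n_per_arm(delta = 0.0750, sd = 0.20, alpha = 0.10)
#> n per arm = 89 (total 178; 198 with 10% attrition inflation)

# the full published-style grid
tab <- build_design_table(effect_grid("dv_hrf"))
subset(tab, alpha == 0.10 & sd == 0.18, c(reduction_pct, cell, cell_inflated))

# simulate a cohort, screen it, and estimate the slope distribution
cfg <- design_config("dv_hrf", n_eyes = 2000, seed = 1)
fit <- hypertd_slopes(simulate_cohort(cfg), "dv_hrf")
print(fit)

# Monte-Carlo power from the empirical zero-inflated slope pool
simulate_power(fit$slopes$slope_mm_per_year, effect_fraction = 0.5,
               n_per_arm = 89, alpha = 0.10, reps = 4000)
```

## Limitations

The generator models one eye per patient (the trial designs enroll a
single study eye), no spatial lesion geometry (only total area), no
bilateral correlation, and no structure–function link. The clinical
exclusion criteria that require chart or image review (myopia, prior
surgery, signal quality) are out of scope of the data model. The
sample-size machinery deliberately stops at the two-sample t test on
slopes: no interim analyses, multiplicity adjustment, or MMRM/joint
longitudinal–survival modeling.
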