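Package: hypertdtrial
Title: Trial Design Modeling for Intermediate AMD Using Hypertransmission
    Defect Growth Endpoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and powering early-phase clinical trials in
    intermediate age-related macular degeneration (iAMD) that use the growth
    of large choroidal hypertransmission defects (hyperTDs) on OCT as a
    continuous structural endpoint. Simulates natural-history cohorts of eyes
    progressing to large hyperTDs, screens them with OCT-biomarker eligibility
    profiles (drusen volume and hyperreflective-foci area), computes
    zero-inflated per-eye least-squares slopes of the square-root total
    hyperTD area, and derives exact noncentral-t and simulation-based sample
    sizes for slope-reduction treatment effects.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    lme4,
    survival
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
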