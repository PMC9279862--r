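Package: ffr3d
Title: In Vitro Style Fractional Flow Reserve from Pressure-Flow Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates fractional flow reserve (FFR) for a stenosed coronary
    vessel from steady-state pressure-flow measurements, the way a bench
    flow-loop study would: replicate pressure-drop versus flow sweeps are
    averaged and fitted with a quadratic-through-origin stenosis law, the
    patient-specific hyperemic operating point is found as the intersection
    of that curve with a maximal-vasodilation coronary flow reserve line
    anchored at the zero-flow pressure, and FFR plus distal microvascular
    resistance follow from the intersection. Includes a synthetic
    hemodynamics generator (viscous plus expansion-loss stenosis model,
    sensor noise, cohort sampling) so the full pipeline is testable without
    bench hardware, and the cohort concordance statistics used to compare
    FFR estimates against an invasive reference: Spearman correlation,
    Bland-Altman limits of agreement with proportional-bias test, paired
    mean comparison, and ROC analysis with DeLong confidence intervals and
    a Youden-optimal threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
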