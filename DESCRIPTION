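Package: dualpet
Title: Dual-Tracer Small-Animal PET Phantom Simulation and Voxel-Wise
    Overlap Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for preclinical dual-tracer positron emission tomography
    (PET) studies of neuroinflammation (TSPO) and amyloidosis. Implements
    reference-region SUVR quantification, whole-brain voxel-wise two-sample
    t-maps with Benjamini-Hochberg false discovery rate thresholding and
    binarization, four-category tracer overlap maps with percent occupancy,
    binary and fuzzy Dice coefficients, inter-age transition flows, and
    terminal fluid-biomarker association statistics (ANOVA with Tukey HSD,
    Lilliefors normality, Pearson correlation, standardized multiple
    regression, standardized-difference timelines, and power-based group-size
    planning). A parametric 3D mouse-brain phantom generator simulates
    cross-sectional transgenic-versus-wild-type cohorts at multiple ages,
    with early widespread inflammation, delayed focal amyloid deposition,
    their late-age spatial convergence, and correlated terminal biomarkers,
    so the full pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
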