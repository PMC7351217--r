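Package: sfamuscle
Title: Spatial Frequency Analysis of Skeletal Muscle Ultrasound
Version: 0.1.0
Authors@R:
    person("SFA", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative texture analysis of B-mode ultrasound images of
    skeletal muscle by spatial frequency analysis (SFA): overlapping square
    kernels inside a polygonal region of interest are zero-padded, Fourier
    transformed, highpass filtered in physical frequency (mm^-1), and
    summarised by four spectral parameters (peak spatial frequency radius,
    Mmax, Mmax percent, Sum) averaged over the region.  Includes the
    reliability toolkit used to validate such measurements (two-way ANOVA
    intraclass correlation coefficients with confidence intervals,
    Sorensen-Dice overlap, standard error of measurement, paired t tests,
    ICC-based sample-size planning), a speckle phantom and ratings-table
    simulator with known ground truth, and a command-line interface.
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
    png,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
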