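Package: dilrepqpcr
Title: Dilution-Replicate Analysis of qPCR Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Efficiency-corrected relative quantification for qPCR
    experiments run in the dilution-replicate design, in which every
    biological replicate is assayed as a short serial-dilution series and
    all samples jointly define the standard curve of each amplicon.
    Provides collinear (shared-slope, per-replicate-intercept) standard
    curve regression, amplification efficiency estimation, outlier
    flagging, weighted predictive-mean-matching imputation of missing
    reference-gene Cq values, geometric-mean normalization against
    multiple reference genes, automated parametric and nonparametric
    group-comparison statistics on log-transformed expression, and
    publication-style plots. A synthetic-data generator with known ground
    truth supports end-to-end validation, and precalculated relative
    expression tables can be fed through the same statistics and plotting
    stages.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
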