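Package: mrdcompare
Title: Head-to-Head Comparison of Single-Target ddPCR and Multitarget
    Sequencing for Circulating Tumour DNA Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing single-target droplet digital PCR (ddPCR)
    and multitarget (16-plex) mPCR-NGS strategies for circulating tumour DNA
    (ctDNA) detection in postoperative minimal-residual-disease monitoring.
    Implements the ddPCR partition model (amplitude thresholding, Poisson
    quantification, reaction QC and merging), blank-derived per-assay noise
    profiles with a four-caller consensus (error-corrected, Poisson,
    beta-binomial and dynamic limit-of-blank callers), the multitarget
    two-of-sixteen positivity rule with mean-of-targets quantification, a
    synthetic patient-cohort generator for paired-aliquot study designs, and
    the associated concordance, specificity, lead-time and
    time-dependent-covariate survival statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
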