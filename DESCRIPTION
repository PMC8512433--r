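Package: vinomix
Title: Integrated Untargeted-to-Targeted GC-MS Workflow for Wine Volatiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated metabolomics workflow for scan-mode GC-MS studies of
    wine volatile compounds. Detects chromatographic peaks on unit-mass extracted
    ion chromatograms, aligns them into a feature-by-sample table, selects
    treatment-significant features by per-factor ANOVA with Benjamini-Hochberg
    false-discovery-rate control, models them with PCA and PLS-DA (leave-one-out
    Q2, VIP scores, permutation validation) and a per-component variance
    partition, annotates features by weighted-cosine spectral library matching
    combined with van den Dool-Kratz retention indices against an n-alkane
    ladder, quantifies confirmed compounds against 1/x-weighted internal-standard
    calibration curves, and ranks compounds by odor activity value. A synthetic
    study generator with known ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mzR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    withr
Config/testthat/edition: 3
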