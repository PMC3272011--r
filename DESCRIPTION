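Package: frcurve
Title: Feature-Response Curves and Multivariate Diagnostics for Genome Assembly Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-free evaluation of de novo genome assemblies from
    amosvalidate-style diagnostic features. Parses per-contig feature files and
    contig lengths, applies point/extent feature counting rules, computes
    Feature-Response Curves (FRC) over the full feature space or any subset,
    and summarizes cohorts of assemblies as an assembly-by-feature matrix.
    The matrix is analyzed by correlation-scale PCA with retention calibrated
    either by an explained-variance threshold or by fitting the
    Marchenko-Pastur eigenvalue law, and a compact informative feature subset
    is selected by kurtosis-ranked independent component analysis (FastICA).
    Feature calls can be validated against true mis-assembly intervals, and a
    synthetic-data module generates assemblies, feature files, truth intervals
    and cohort matrices with planted statistical structure for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    IRanges
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
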