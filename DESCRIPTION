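Package: cghdiverge
Title: Array-CGH Strain Divergence Profiling and Karyotype Fingerprinting
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for genome-wide strain comparison from array-based
    comparative genomic hybridization (array-CGH) log2 ratios: cohort-average
    re-normalization, per-gene divergence (standard deviation) profiles with
    moving-average smoothing, penalized least-squares segmentation of
    copy-number profiles, selection of divergent genes by a global
    k-standard-deviation exceedance rule, hypergeometric functional-category
    overrepresentation with Benjamini-Hochberg FDR control, complete-linkage
    strain clustering, and electrophoretic-karyotype (PFGE band pattern)
    similarity via band binning, Jaccard coefficients and UPGMA. Includes a
    synthetic-cohort generator with planted subtelomeric copy-number events,
    reference-strain hybridization bias and matched band patterns, so every
    stage is testable against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
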