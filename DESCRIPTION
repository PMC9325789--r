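Package: depscreen
Title: Unified Gene-Dependency Screens and Survival-Based Target Prioritisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for prioritising candidate drug targets from large-scale
    genetic perturbation screens. Unifies CRISPR knockout and shRNA knockdown
    gene-effect matrices into a single perturbation score via loess imputation
    of missing values and a principal-component-guided mixing ratio, calls
    lineage-specific essential genes by fitting a Gaussian to the kernel
    density of percentile efficacies and thresholding its lower tail, scores
    cell-line selectivity from dispersion residuals, tests gene sets for
    hypergeometric over-representation, and relates tumour expression of
    shortlisted genes to patient survival across cohorts using
    covariate-adjusted Cox models pooled by DerSimonian-Laird random-effects
    meta-analysis with Benjamini-Hochberg false-discovery control. A
    synthetic-data module simulates coupled two-platform screens and
    multi-cohort survival data with known ground truth so every stage of the
    pipeline can be exercised and calibrated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    metafor
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
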