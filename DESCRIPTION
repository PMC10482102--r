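Package: taxaMR
Title: Two-Sample Mendelian Randomization of Gut Microbial Taxa on Disease Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A complete two-sample Mendelian randomization workflow for
    linking gut-microbiota taxon abundance (exposure GWAS summary
    statistics) to disease risk (case-control outcome GWAS summary
    statistics). Covers instrument selection with p-value screening,
    greedy LD clumping against a reference dosage panel and an
    F-statistic strength filter; allele harmonization with palindrome
    exclusion; inverse-variance-weighted, MR-Egger, weighted-median,
    maximum-likelihood and Wald-ratio causal estimators; Cochran's Q
    heterogeneity tests, the Egger intercept test, MR-PRESSO outlier
    detection, leave-one-out and funnel diagnostics; and
    Benjamini-Hochberg FDR control across taxa. Includes a synthetic
    summary-statistics generator with known ground truth so every stage
    is testable without access to the original cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
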