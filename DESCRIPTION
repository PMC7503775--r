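Package: phenolomics
Title: UPLC-PDA Phenolic Profiling with Drought-Effect Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of ultra-performance liquid chromatography
    photodiode-array (UPLC-PDA) phenolic metabolite profiles from designed
    stress experiments. Implements the chromatographic preprocessing chain
    (sample-mass normalization, baseline removal by numerical
    differentiation, correlation optimized warping for retention-time
    alignment, peak detection on spline-smoothed second derivatives,
    cross-sample common-peak construction and integration, dual-wavelength
    merging), factorial ANOVA classification of drought effects with
    per-family Bonferroni control, treatment-effect profiles with
    maximum-between-group-sum-of-squares clustering and Mahalanobis
    distances, permutation chi-square tests on category tables, phenotype
    effect classification, biplots and metabolite-phenotype effect
    correlations, and neutral-loss mass arithmetic for annotating flavonoid
    glycoconjugate MSn spectra. A synthetic-data generator emulates the
    full experimental design (varieties x moisture-deficit treatments x
    time points x replicates) with known ground truth so that every stage
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
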