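Package: colonykin
Title: Fine-Scale Spatial and Temporal Genetic Structure of Breeding Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for within-colony population genetics from codominant
    microsatellite genotypes with nest coordinates, hatch dates, sex and
    group labels. Implements marker quality control (Monte-Carlo exact
    Hardy-Weinberg and linkage-disequilibrium tests, false discovery rate
    control, null-allele and duplicate-genotype error estimation), four
    moment estimators of pairwise relatedness (Wang; Queller-Goodnight;
    Lynch-Ritland; Li similarity index) with dyad simulation for estimator
    comparison, Ritland's method-of-moments individual inbreeding
    coefficient, standardized genetic differentiation (Hedrick/Meirmans
    G''ST) with permutation tests and locus bootstraps, Evanno delta-K
    post-processing of external clustering runs, multilocus spatial
    autocorrelation correlograms with the Smouse-Peakall omega
    heterogeneity test, sex-stratified comparison, two-dimensional local
    spatial autocorrelation, within/between-group relatedness permutation
    tests, breeding-timing classes by k-means with class-wise
    differentiation, Mantel tests, and ladder-of-powers (Tukey)
    transformed regressions. A synthetic-colony generator with
    controllable kin clusters, temporal divergence and genotyping noise
    makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
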