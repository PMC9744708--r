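Package: hescale
Title: Cross-Study Standardization of Microsatellite Expected Heterozygosity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardizes expected heterozygosity (He) computed from nuclear
    microsatellite panels of differing polymorphism so that values are
    comparable across studies. Implements theorem-based theoretical bounds on
    homozygosity given the number of alleles and the frequency of the most
    frequent allele, min-max scaling of homozygosity within those bounds,
    merging of multi-study genotype or allele-frequency data into a
    meta-dataset, geographic gradient analysis (Spearman correlations against
    latitude, longitude and distance from a hypothesized origin),
    resampling-based ascertainment-bias validation scenarios,
    inverse-distance-weighted spatial interpolation with leave-one-out
    cross-validation and jackknife confidence intervals, and a synthetic
    range-expansion data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    geosphere,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
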