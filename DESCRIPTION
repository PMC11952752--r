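Package: rootshoot
Title: Root and Shoot Quantification from Agar-Plate Images of Seedlings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments flat-bed scans of agar-grown Arabidopsis seedlings into
    root (white), shoot (green) and background (blue) pixels by color-space
    thresholding, extracts individual plants by connected-components analysis,
    and records per-plant projected areas. Downstream utilities fit exponential
    growth rates by log-linear regression, compute salt tolerance indices,
    test salt-induced expansion of the variance of the root:shoot growth-rate
    ratio, estimate broad-sense heritability from variance components, and
    support post-GWAS candidate prioritization: minor-allele-count stratified
    Bonferroni thresholds, locus clustering, and haplotype grouping with
    ANOVA and Tukey HSD compact letter displays. Ships seed-deterministic
    synthetic generators (plate images, growth series, genotype tables) with
    exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    stats,
    tools,
    utils,
    png,
    jpeg,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
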