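Package: adipoclock
Title: Aging-Clock Analysis of Heterochronic Adipose Tissue Transplants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal tissue-age analysis of heterochronic and
    isochronic white adipose tissue (WAT) transplantation experiments. Applies
    linear aging and mortality clocks to methylation beta-value and bulk
    RNA-seq count matrices with RLE normalization, log transformation,
    per-feature scaling, clock-feature imputation and reference-median
    centering; quantifies within-donor Before/After age dynamics and
    between-group dynamic differences with paired and mixed-effects models;
    calibrates predicted ages against sham-operated controls; decomposes
    linear-clock predictions into additive per-gene contributions with an
    exact conservation identity; screens genes for association with tissue-age
    dynamics; and quantifies adipose histology (lipid droplet morphometry,
    collagen fraction, 3D mitochondrial volume and sphericity) from RGB
    sections and labeled volumes. A synthetic-data generator emulates the
    four-group transplant design with planted clock signal, negative-binomial
    count noise and rendered histology, so every stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    lme4,
    lmerTest,
    EBImage,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
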