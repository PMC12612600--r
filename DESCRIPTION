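Package: orchardspec
Title: Genomic Heritability of Needle Traits and Reflectance in Clonal Seed Orchards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of clonal seed orchard trials with
    genomic relationship matrices. Simulates clonally replicated orchard
    designs with spatially autocorrelated residuals, builds marker-based
    relationship matrices (Yang et al. estimator) from SNP dosage data with
    standard quality filters, computes needle functional traits (pigments,
    leaf mass per area, water content) and preprocesses hyperspectral
    reflectance, and fits multi-site and bivariate genomic mixed models by
    restricted maximum likelihood with separable AR1-by-AR1 spatial residuals
    to estimate broad-sense heritability, type B and trait-pair genetic
    correlations, and clonal BLUP rankings, including per-wavelength scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse,
    vcfR
Config/testthat/edition: 3
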