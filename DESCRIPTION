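Package: jointsfs
Title: Joint Site Frequency Spectrum Demographic Inference for Two Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring two-population demographic history from SNP
    genotype matrices via the joint (2D) site frequency spectrum. Includes a
    structured-coalescent simulator with epochs of size change and asymmetric
    migration, the site filters used in reduced-representation (RAD-style)
    population genomics (call rate, minor allele frequency, excess
    heterozygosity), folded 2D-SFS construction with hypergeometric projection
    and contig bootstrapping, a deterministic moment-equation engine for the
    expected SFS under a catalog of isolation-with-migration models, Poisson
    composite-likelihood fitting with multi-start optimization, median-AIC
    model ranking with AIC weights, conversion of fitted parameters to
    physical units, and population-structure summaries (identity-by-state
    distances, principal coordinates analysis, PERMANOVA, Hudson FST).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vegan,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
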