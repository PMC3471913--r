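Package: rhm
Title: Regional Heritability Mapping from Genome-Wide SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genome scans for regional heritability: variance-component
    mixed models that fit a whole-genome relationship matrix together with
    a window-specific (regional) relationship matrix built from runs of
    adjacent SNPs, estimated by average-information REML and tested with a
    boundary-mixture likelihood-ratio test.  Includes PLINK binary
    genotype input and quality control, allele-frequency-weighted IBS
    kinship and GRM construction, sliding-window scans with multi-region
    joint models and SNP-covariate adjustment, a single-SNP mixed-model
    score test for comparison, permutation null distributions and
    threshold calculations, QTL power simulation, and a gene-dropping
    simulator of population-isolate samples for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
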