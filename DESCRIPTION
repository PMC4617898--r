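Package: eggqtl
Title: Daughter-Design QTL Mapping with QTL-by-Environment Interaction
    Tests for Egg Production and Quality Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for daughter-design genome-wide
    association studies in layer chicken breeding. Genotyped sires are
    evaluated through the adjusted phenotypes of their crossbred daughters
    housed in collective cages under two diets, with egg quality measured at
    two ages. Provides sequential SNP quality control (call rate, minor
    allele frequency, Hardy-Weinberg), per-hatch fixed-effect phenotype
    adjustment with P < 0.2 submodel selection and 4-SD trimming, the
    pedigree additive relationship matrix, a single-marker mixed-model scan
    with REML variance components, Monte-Carlo chromosome-wide and
    Bonferroni genome-wide significance thresholds, QTL calling with
    confidence intervals and variance explained (2p(1-p)alpha^2), and Z and
    Fisher tests for QTL-by-diet and QTL-by-age interactions, including
    within-condition scans for additional QTL. A synthetic-data generator
    reproduces the design, including planted QTL whose allele-substitution
    effects differ between conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
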