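Package: mtphewas
Title: Mitochondrial Phenome-Wide Association with Polygenic Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage mitochondrial phenome-wide association (mt-PheWAS)
    analysis. Builds a nuclear additive genetic relationship matrix (GRM) and a
    haploid allelic-sharing mitochondrial GRM from PLINK binary genotypes, fits
    a two-variance-component mixed linear model by EM-REML to estimate the
    proportion of phenotypic variance explained by each genome, prioritizes
    phenotypes with a boundary likelihood-ratio test on the mitochondrial
    component, and runs covariate-adjusted single-mtSNP association scans.
    Includes electronic-health-record style phenotype aggregation
    (median-of-yearly-medians, hypertension dichotomization) and a synthetic
    data generator with known variance architecture for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
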