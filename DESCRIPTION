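Package: duomr
Title: Within-Family Mendelian Randomization in Genotyped Parent-Child Duos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for disentangling maternal (intrauterine) from fetal
    (pleiotropic) genetic effects on later-life disease using polygenic
    scores for birth weight in genotyped mother-child, father-child and
    full-sibling pairs. Provides a synthetic family-cohort generator with
    Hardy-Weinberg parental genotypes and per-locus Mendelian transmission,
    unweighted and weighted polygenic score construction, single-score and
    joint mother+child logistic association models with attenuation
    diagnostics, conditional logistic regression on disease-discordant
    same-sex sibling pairs, and a simulation-based power analysis for the
    joint model, including minimum-detectable-odds-ratio search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    statmod,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
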