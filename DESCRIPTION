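Package: sexvar
Title: Sex-Specific Selection and the Genetic Architecture of Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic two-sex population genetics of disease-predisposing
    alleles. Solves per-locus equilibrium allele frequencies under
    sex-differential (including sexually antagonistic) viability selection with
    recurrent one-way mutation, classifies the selection regime
    (mutation-selection balance, balancing selection, disease fixation), and
    partitions sex-specific additive genetic variance across classes of
    between-sex effect asymmetry (t/s) for mutation sets drawn from a
    correlated bivariate gamma distribution of fitness effects. Includes a
    seeded sampler for three bivariate-gamma constructions (Kibble,
    trivariate reduction, Gaussian copula), Monte-Carlo evaluation of the
    covariance criterion for disproportionate contribution of asymmetrically
    selected loci, tidy and ggplot2 interfaces, and a command-line entry
    point.
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
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
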