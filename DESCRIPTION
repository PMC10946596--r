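Package: mbfact
Title: Two-Way Factorial Analysis of Gut Microbiome Counts and Clinical Markers
Version: 0.1.0
Authors@R:
    person("Charl", "Moller", email = "charl.moller@example.org", role = c("aut", "cre"))
Description: Tools for two-way factorial (e.g. HIV status by iron status)
    case-control analysis of genus-level 16S gut-microbiome count tables and
    accompanying clinical markers. Provides a ground-truth synthetic cohort
    generator with compositional counts and zero inflation; prevalence
    filtering, rarefaction and centred log-ratio transforms; Shannon and
    Bray-Curtis diversity with Kruskal-Wallis/Dunn group tests and principal
    coordinate analysis; redundancy-analysis effect sizes on CLR data with
    forced-feature forward selection; five nested Bayesian binomial abundance
    models fitted by adaptive MCMC with WAIC model selection and 94% highest
    density interval percent-change summaries; a zero-inflated Dirichlet-weight
    prevalence mixture model; BRINDA ferritin adjustment and unbalanced
    two-way factorial ANCOVA/logistic tests with Bonferroni chi-squared post
    hoc letters; and a pipeline driver that writes tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
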