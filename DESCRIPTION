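Package: gefam
Title: Gene-Environment Interaction Tests for Longitudinal Twin-Family Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for detecting gene-environment (GE)
    and gene-time-environment (GTE) interactions in longitudinal twin-family
    data. Provides a twin-cohort trajectory simulator (Mendelian genotypes,
    binary exposures, segmented BMI growth curves with ACE-structured random
    intercepts and slopes), three analysis methods -- a maximum-likelihood ACE
    twin path model on time-averaged outcomes, a linear mixed model on all
    repeated measures with a kinship-structured random intercept, and the
    nonparametric partition-based score I (PBI) test with family-constrained
    permutation -- and replicate runners for Monte-Carlo type-I-error and
    power studies across linear and non-linear interaction scenarios.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
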