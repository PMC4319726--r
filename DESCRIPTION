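Package: snpcc
Title: Case-Control SNP Association Analysis with False-Positive Report
    Probability
Version: 0.1.0
Authors@R:
    person("snpcc", "maintainers", email = "snpcc@example.org",
           role = c("aut", "cre"))
Description: Tools for candidate-SNP case-control association studies:
    Hardy-Weinberg equilibrium testing in controls, crude and
    covariate-adjusted odds ratios under codominant, dominant and recessive
    genetic models with Woolf confidence intervals, combined risk-genotype
    profiling, stratified analyses with Cochran Q heterogeneity and
    likelihood-ratio interaction tests, and false-positive report
    probability (FPRP) with power calculation against a target odds ratio.
    Includes a reproducible case-control cohort simulator (marginal and
    causal modes) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
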