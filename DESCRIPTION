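Package: mrpath
Title: Two-Sample Mendelian Randomization with Mediation and Bayesian Model Averaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for genetic causal inference from GWAS
    summary statistics. Implements harmonization of exposure and outcome
    association statistics to a common effect allele, instrument selection by
    p-value thresholding, greedy LD clumping, instrument-strength (F-statistic)
    filtering and confounder-SNP exclusion, five univariate two-sample
    Mendelian randomization estimators (Wald ratio, random-effects IVW,
    MR-Egger, weighted median, simple and weighted mode) with a full
    sensitivity battery (Cochran's Q heterogeneity test, MR-Egger intercept,
    the three-step MR-PRESSO residual-sum-of-squares procedure, and Steiger
    directionality), multivariable MR via Bayesian model averaging (marginal
    inclusion probabilities, model-averaged causal effects, permutation
    p-values), and two-step mediation decomposition of exposure to mediator to
    outcome pathways (indirect effect, proportion mediated, sign-consistency
    screening). A synthetic summary-statistics generator with known ground
    truth supports testing of every stage without external data.
License: MIT
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
    yaml,
    optparse
Config/testthat/edition: 3
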