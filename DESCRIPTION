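Package: ebfactor
Title: Bias-Corrected Posterior Bayes Factors from Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes empirical Bayes factors (EBFs): posterior Bayes factors
    corrected for the expected bias incurred by using the data twice, so that
    they are interpretable on the scale of ordinary Bayes factors. Covers
    normal (z and chi-squared), Student t, binomial and negative binomial,
    F/ANOVA and P-value-only summary statistics, point, one-sided, interval
    and unrestricted hypotheses, a mixture-posterior extension for multiple
    testing, and an evidence-unit scale with base 2+sqrt(3). Includes exact
    and quadrature evaluation of the expected-bias tables, Monte Carlo
    validation oracles, simulation studies of limited and large-scale
    multiplicity, and delimited-table input/output for pipeline use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
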