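Package: fakemix
Title: Faking Mixture Models for Multidimensional Forced-Choice Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the Faking Mixture model, an item response model for faking
    on multidimensional forced-choice (MFC) questionnaires. Rank-order
    responses in a high-stakes administration are modelled as a mixture of an
    honest process, governed by a Thurstonian item response model fixed from a
    low-stakes administration, and a faking process, governed by block-level
    rank-order desirability parameters. The model yields a derived fakability
    parameter per block, a person-level faking trait with a probit link, and
    rank-order desirability profiles. Includes the Thurstonian rank-order
    probability engine (multivariate-normal orthant integration), a synthetic
    data generator covering a crossed fakability by faking-trait design,
    Bayesian estimation by adaptive Markov chain Monte Carlo with convergence
    diagnostics, a multigroup variant for comparing questionnaire versions,
    and a parameter-recovery study harness with an ANOVA-style variance
    decomposition of recovery metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    graphics,
    mvtnorm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
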