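Package: hetlogit
Title: Mixed Logit Models with Flexible Mixing Distributions and Model
    Averaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation and comparison of random preference heterogeneity
    in discrete choice models for health applications. Implements maximum
    simulated likelihood for panel mixed logit under seven parametric
    mixing distributions (normal, uniform, triangular, log-normal,
    log-uniform, asymmetric triangular, and second- and third-order
    polynomial expansions), modified Latin hypercube sampling draws,
    willingness-to-pay-space utility specifications, a bivariate
    revealed-preference logit with a correlated individual error
    component, and sequential latent-class model averaging over fitted
    models. Post-estimation tools cover sample enumeration of choice
    probabilities, unconditional preference and willingness-to-pay
    distributions, and model-comparison tables. A synthetic-data module
    simulates drug-choice experiments and correlated binary outcomes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
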