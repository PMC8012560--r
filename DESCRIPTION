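Package: netresil
Title: Resilience Analysis of Ising Symptom Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models psychiatric symptom dynamics as an Ising network whose
    parameters are perturbed multiplicatively by risk and protective factors,
    and quantifies resilience with two metrics: Expected Symptom Activity
    (ESA), the expected sum score of active symptoms, and Symptom Activity
    Stability (SAS), the inverse standard deviation of the sum score.
    Provides exact enumeration of small networks, single-site
    Metropolis-Hastings/Gibbs sampling for larger ones, nodewise
    L1-penalized logistic regression with EBIC selection for estimating
    networks from binary data, node-strength-targeted perturbation sweeps,
    and conditioning of hybrid symptom plus risk/protective-factor networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
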