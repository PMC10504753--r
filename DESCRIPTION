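Package: symptomnet
Title: Regularized Symptom Networks for Comorbid Anxiety and Depression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Screening, descriptive comparison, and regularized
    partial-correlation network analysis of ordinal questionnaire data,
    built around comorbid anxiety (GAD-7) and depression (PHQ-9) symptoms
    in survivors of childhood sexual abuse screened with the CTQ-SF.
    Provides a latent-Gaussian ordinal cohort simulator with planted
    network structure, subscale scoring with clinical cut-offs and
    prevalence intervals, Table-1 style group comparisons, graphical
    LASSO estimation with EBIC penalty selection, expected-influence and
    bridge centrality with nodewise predictability, a permutation network
    comparison test with Holm correction, and bootstrap accuracy and
    case-dropping stability diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    mvtnorm,
    jsonlite,
    yaml,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
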