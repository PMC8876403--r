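Package: drabc
Title: Hierarchical Neural-Network Risk Prediction of Germline Pathogenic
    Variant Carrier Status in Breast Cancer Patients
Version: 0.1.0
Authors@R: person("drabc", "developers", role = c("aut", "cre"),
    email = "drabc@example.org")
Description: Phenotype-based prediction of germline pathogenic variant (GPV)
    carrier status for breast cancer patients. Implements a hierarchical
    two-output neural network over 25 encoded clinical features that yields,
    via the probability chain rule, the probability of carrying a GPV in any
    cancer predisposition gene, in BRCA1/2 specifically, or in another
    predisposition gene; an ensemble (bagging) training scheme with
    sensitivity-targeted cutoff selection; comparator baselines (an NCCN-style
    rule engine, logistic and naive-Bayes reconstructions); ROC/AUC machinery
    with DeLong confidence intervals and paired tests; and a synthetic cohort
    generator driven by published genotype-conditional phenotype frequencies
    so the full pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
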