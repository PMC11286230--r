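Package: einvpolicy
Title: Effect-Invariance Testing and Policy Generalization Across Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tests whether conditional average treatment effects (CATEs) are
    invariant across environments (effect-invariance) and exploits such
    invariances for policy learning. Provides a linear-CATE Wald test built on
    centered, propensity-weighted estimating equations with a sandwich
    covariance, a nonparametric doubly-robust pseudo-outcome test based on a
    multi-environment generalised covariance measure, zero-shot policy
    learning that selects an effect-invariant covariate subset and deploys its
    argmax policy in an unseen environment, few-shot constrained CATE
    estimation in a test environment under a separability assumption, seeded
    structural-causal-model simulators with ground-truth CATE oracles
    (including a micro-randomized-trial-like multi-user fixture), and a
    residual-bootstrap policy-value evaluator with leave-one-environment-out
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    mgcv,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
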