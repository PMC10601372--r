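Package: levercode
Title: Encoding and Decoding of Motor Cortex Population Activity in a
    Lever-Pull Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling how sparse, binarized single-neuron activity
    in motor cortex relates to skilled forelimb behavior in head-fixed mice.
    Implements a Bernoulli elastic-net generalized linear encoding model over
    Gaussian temporal basis expansions of 20 behavioral variables, imbalanced
    10-fold cross-validation with temporal leakage guards, encoding unique
    contributions and kernel-consistency statistics, normalized-rank stability
    tests against resampled populations, and a Bayesian marginalization
    decoder of the lever trajectory from population activity. A synthetic
    session generator reproduces the statistical structure of self-initiated
    and target-zone lever-pull tasks (trial state machines, reward-coupled
    orofacial dynamics, sparse Bernoulli activity from known ground-truth
    kernels) so that every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
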