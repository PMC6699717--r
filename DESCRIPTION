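Package: pulsedesign
Title: Optimal Design and Rate Estimation for Metabolic RNA Labeling Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for planning and analysing metabolic RNA labeling
    experiments (4sU pulse/chase, SLAMseq-style nucleotide conversion and
    biochemically separated fractions). Implements first-order kinetic mean
    models for labeled, unlabeled and total RNA fractions, Fisher-information
    computation under Poisson and negative-binomial read-count models,
    solvers for asymptotically optimal labeling and chase times, design
    evaluation across gene panels, depth-versus-replicates tradeoffs,
    maximum-likelihood estimation of per-gene degradation rates with shared
    overdispersion and fraction normalization coefficients, Wald and
    profile-likelihood confidence intervals, and a reproducible count
    simulator for power and coverage studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
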