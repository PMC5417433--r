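Package: hostcol
Title: Stage-Wise Host-Colonization Analysis for Bark Beetle Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical machinery for multi-stage host-colonization
    experiments with bark beetles: stage-wise binomial success estimation on
    the logit scale with Haldane-corrected Wald intervals, logistic regression
    with likelihood-ratio contrasts, a logit-normal Monte Carlo integration of
    colonization stages into an overall susceptibility distribution, a
    squared-rank-difference permutation test of between-year treatment-ranking
    concordance (with an exact enumeration oracle), transform + ANOVA +
    protected-LSD analysis of trap-catch and phloem-chemistry data with
    compact letter displays, a Bonferroni indicator-variable outlier scan, and
    seeded hierarchical simulators of colonization trials, overdispersed trap
    counts and lognormal monoterpene concentrations so every analysis is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
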