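---
title: "Stage-wise colonization analysis: models, conventions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-wise colonization analysis: models, conventions, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostcol)
```

`hostcol` analyses staged host-colonization assays: a bark beetle must bore
through the outer bark, initiate a tunnel in the phloem, and establish an
ovipositional gallery with brood before colonization counts as successful.
Each stage is a binomial experiment on assay units nested in logs/trees.
This vignette records the models, the numerical conventions, and the design
choices made where more than one defensible convention exists.

## Stage-wise binomial estimation

For $k$ successes of $n$ exposures the logit-scale estimate is the
saturated-binomial MLE,
$$\hat\mu = \ln\frac{k}{n-k}, \qquad
  \widehat{se} = \sqrt{\tfrac1k + \tfrac1{n-k}},$$
the delta-method standard error from the observed information. 95%
intervals are $\mathrm{logit}^{-1}(\hat\mu \pm 1.96\,\widehat{se})$:
asymmetric about $\hat p$ except at $p = 0.5$, and always strictly inside
$(0,1)$.

**Boundary counts.** At $k = 0$ or $k = n$ the logit diverges; we apply the
Haldane–Anscombe correction (add $0.5$ to each cell) before the logit
computation and flag it (`correction_applied`). The reported `p_hat` stays
the raw $k/n$ — so a boundary estimate of exactly 0 or 1 sits outside its
own corrected interval, which brackets the corrected proportion instead.
This is deliberate: the raw ratio is the honest point estimate, while the
corrected interval is the honest uncertainty statement.

**Covariates.** `fit_logistic()` fits grouped binomial GLMs (IRLS, relative
tolerance $10^{-10}$, at most 100 iterations) and `lrt_nested()` compares
nested fits by likelihood ratio. Separation is reported, not hidden: any
coefficient beyond 15 logits marks the fit `converged = FALSE`.

**Random effects are simulated, not fitted.** The data-generating model has
tree and unit-within-tree Gaussian random effects on the logit scale, and
the simulator draws them; the estimators, however, are fixed-effects on
unit-level counts. Two reasons: the Monte Carlo integrator needs only
per-species logit means and SEs, which the saturated estimates supply
directly; and a variance-component fit would add machinery without changing
those inputs in balanced designs. Users needing cluster-robust SEs can
resample trees. The cost of the approximation is that with strong tree
effects, the saturated SE understates between-tree uncertainty — interval
coverage in the test suite is therefore checked under the no-random-effect
condition it is claimed for.

## Susceptibility integration

The three per-species stage estimates are combined by Monte Carlo:
$$S = \prod_{j=1}^{3} \mathrm{logit}^{-1}(\hat\mu_j + \widehat{se}_j Z_j),
  \qquad Z_j \sim N(0,1) \text{ independent},$$
with 100,000 draws per species by default, summarised by the median and the
middle 95% (empirical 2.5th–97.5th percentiles).

Choices worth recording:

- **Scale of multiplication.** The stage distributions could be multiplied
  on the logit or the probability scale; a product of logits has no meaning
  as a passage probability, so draws are back-transformed *before*
  multiplying. In the zero-variance limit every draw equals
  $\prod_j \mathrm{logit}^{-1}(\hat\mu_j)$ exactly.
- **Independence.** Stages are drawn independently. In reality a vigorous
  tree could depress all three stages at once; no correlation structure is
  modelled, so the spread of $S$ is, if anything, understated.
- **Percentile convention.** Linear interpolation between order statistics
  (`quantile` type 7), configurable in `truncate_middle()` because no single
  convention is universal; retained draws are those strictly inside the two
  bounds.
- **Common random numbers.** The $Z$ draws are generated before being
  scaled by the stage parameters, so equal seeds share randomness across
  parameter sets; raising one stage's logit mean then raises every draw, a
  property the tests exercise directly.
- **Substreams.** Per-species seeds derive from a master seed via
  `substream_seed()`, so species results do not depend on evaluation order.

## Ranking concordance

Two years' treatment rankings (rank 1 = most attractive, i.e. largest mean
catch) are compared with $D = \sum_i (r_{1i} - r_{2i})^2$, which is 0 for
identical rankings and $k(k^2-1)/3$ for full reversal. The null randomizes
*both* rankings uniformly, 999 replicates by default, with
$$p = \frac{1 + \#\{D_{\text{rand}} \le D_{\text{obs}}\}}{n_{\text{reps}}+1}.$$

- "$\le$" defines extremeness because small $D$ means *similarity*, which
  is what is being tested; the $+1$ correction counts the observed
  statistic and guarantees $p > 0$.
- Ties get average ranks for the statistic; the exact oracle refuses ties
  rather than approximating.
- `exact_pvalue()` enumerates all $k!$ permutations with one ranking held
  fixed, valid because $D$ depends only on the relative permutation; the
  equivalence of fixing one ranking versus randomizing both is itself a
  tested property (enumerated at $k = 4$), not an assumption.

## ANOVA, protected LSD, outliers

Trap counts are square-root transformed before ANOVA, as is 4-allylanisole;
β-pinene, 3-carene, myrcene, limonene, β-phellandrene and camphene are
log(y+1) transformed; α-pinene is analysed untransformed
(`transform_registry()`).

**Blocks.** Site and week enter `blocked_anova()` as additive *fixed*
factors. With balanced designs this gives the same treatment F as a mixed
model with random blocks; the simplification keeps the module
dependency-light and is recorded in the result's `method` field. No
REML/variance components are estimated.

**Summary-statistics ANOVA.** `anova_from_summary()` rebuilds a balanced
one-way ANOVA from printed group means and SEs: $MS_B = n\sum_i(m_i-\bar
m)^2/(k-1)$ and $MS_W = \text{mean}(n \cdot se_i^2)$. It is
property-tested to agree with the raw-data ANOVA to $10^{-10}$ relative
tolerance on balanced data, and is how a published table of means (SE) is
turned back into its omnibus F.

**Protected LSD.** Pairwise comparisons run only when the omnibus F is
significant at $\alpha$ (default 0.05); otherwise all groups share one
letter — so a non-significant omnibus can never produce separated means.
Significant pairs use the unequal-$n$ Fisher LSD with the pooled $MS_W$.
Letters come from an insert-and-absorb pass in descending-mean order; the
letter count is not guaranteed globally minimal, which matters only
cosmetically.

**Outlier scan.** Each candidate observation gets a one-hot indicator added
to the linear model; it is an outlier when the indicator's p-value is below
$\alpha/N$ with $N$ the total observations in that fit (Bonferroni over all
observations, candidate included). The scan is single-pass in candidate
order with refit after each removal; order and iteration policy are
arguments because different labs iterate differently. In the pipeline,
default candidates are counts more than 3 pooled SDs above their
treatment-year mean on the transformed scale.

## What the simulators emulate — and what they do not

`simulate_colonization()` reproduces the *structure* of the staged assays:
species-specific stage intercepts, a phloem-thickness slope (logit units
per mm), tree and unit random effects, and per-year design blocks
(trees × units × beetles per unit; the default mirrors 2 trees × 10 cells
× 5 beetles and 3 trees × 2 cells × 15 beetles). The design block is an
explicit parameter rather than a hard-coded exposure total because the
published per-species exposure arithmetic cannot be reconstructed uniquely
from the printed design constants; a `paired_male` field is recorded
because brood denominators may or may not be restricted to male-paired
galleries. Default stage intercepts are calibrated to pooled rates of
0.633 (bark), 0.847 (phloem) and 0.702 (brood).

`simulate_traps()` uses a gamma-Poisson construction
($Var = \lambda + \phi\lambda^2$) so the square-root transform has real
work to do, with lognormal site and week blocks; default treatment
log-means are ordered ponderosa ≥ scots > lodgepole ≈ jack ≈ red > eastern
white ≈ control. `simulate_chemistry()` draws lognormal concentrations per
species × tree × compound.

Not emulated: beetle flight and pheromone plume dynamics, tree mortality,
within-season temporal structure in trap catches, correlated stages within
a tree, or GCMS signal processing. Passing tests therefore demonstrate
that the *estimators* behave correctly under the stated generating model —
they do not validate that model against field data.

## Problem sizes and tolerances in the test suite

The suite uses sizes chosen to make sampling error negligible relative to
the assertion: 10,000 exposures for law-of-large-numbers checks (3
binomial-SE bands), 100,000 draws for Monte Carlo means (3 MC-SE bands),
99,999 permutation replicates against exact enumeration (3 binomial-SE
bands), 500 replicates at $n = 140$ for 95% ± 3% interval coverage, 200
random balanced datasets for the summary-vs-raw ANOVA identity
($10^{-10}$ relative), and 200 null datasets for the LSD protection
property (zero violations allowed). Deterministic identities (transform
arithmetic, closed-form logits, enumeration probabilities) are asserted to
floating-point tolerance.

## Known limitations

- Fixed-effects estimation understates SEs under strong tree-level
  clustering (see above); no quasi-likelihood or overdispersion correction
  is applied to the binomial fits.
- The blocked ANOVA's fixed-block approximation diverges from a true mixed
  model in unbalanced designs.
- The exact concordance oracle stops at $k = 8$ ($k!$ growth); beyond that
  only the Monte Carlo path is available.
- Printed χ² values from the original mixed-model analyses of the
  motivating experiments are not reproducible here or anywhere: the
  underlying raw data were never published. The package reconstructs what
  is reconstructable from summary statistics and makes the rest testable
  by simulation.
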