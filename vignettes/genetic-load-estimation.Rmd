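---
title: "Estimating genetic load from line-extinction experiments"
author: "nemaload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genetic load from line-extinction experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemaload)
```

## The experimental design and its statistical structure

A line-extinction experiment propagates on the order of a hundred
independent lines of an obligately outcrossing nematode strain by serial
single-pair brother–sister matings, for up to 20 generations. Every
cross either produces the L4 male and female that found the next
generation, or it fails and the line is extinct. The data are therefore
one Bernoulli outcome per cross, indexed by the inbreeding coefficient
*F* of the crossed parents, plus — when the failure step was recorded —
three sequential conditional sub-outcomes: copulation, fertility given
copulation, and development given fertility.

### Inbreeding coefficients

`sib_mating_F()` implements the textbook full-sib recursion
$F_t = \tfrac14(1 + 2F_{t-1} + F_{t-2})$ with boundary
$F_0 = F_{-1} = 0$. The boundary encodes the design: lines are founded
from a large outbred population, so the founding pair is unrelated and
non-inbred, and the first sib mating yields offspring with $F_1 = 0.25$.
Writing $y_t = 1 - F_t$ turns the recursion into the linear form
$y_t = \tfrac12 y_{t-1} + \tfrac14 y_{t-2}$, whose dominant root
$(1+\sqrt5)/4 \approx 0.809$ is the asymptotic per-generation retention
of heterozygosity; the test suite checks both the equivalence of the two
forms (to $10^{-12}$ over 50 generations) and the convergence of the
ratio (to $10^{-6}$ by generation 30).

`parental_F()` maps experiment generations to the F of the *crossed
parents*: generations 1 and 2 pair non-inbred individuals (the offspring
of unrelated parents are themselves non-inbred), and generation
$g \ge 3$ pairs siblings carrying $F_{g-2}$. We attach this parental F
to each cross record because the model describes the probability that a
*pair* with a given F reproduces; the two-generation offset is handled
inside the package rather than left to callers precisely because it is
the easiest thing to get wrong when assembling data.

Values are kept in double precision; no rational-arithmetic mode is
provided since the analysis needs F to about six decimals at most.

### The load regression

Cross success is modelled as binomial with
$\ln(R/(1-R)) = \beta_0 + \beta_1 F$, fitted by maximum likelihood
(`stats::glm`, logit link; IRLS tolerance $10^{-8}$, at most 100
iterations). The coefficients convert to load parameters on the
reproducing-pair scale,
$A_R = -\ln R_{F=0}$ and $B_R = -\ln(R_{F=1}/R_{F=0})$, computed through
`log1p` for numerical stability at large $|\beta|$. The inverse map
`beta_from_load()` exists for round-trip checking and for building
simulation configurations from load values; the suite verifies the round
trip to $10^{-10}$ over 1000 random coefficient pairs.

The significance screen for concealed load is a two-sided Wald z-test of
$\beta_1 = 0$, matching the conventional `summary(glm())` output; a
likelihood-ratio test would be more powerful near separation but is not
what load tables conventionally report, so it is not fitted by default.

Degenerate data — all successes, all failures, or complete/quasi-complete
separation of successes and failures along F — are reported as classed
errors (`nemaload_degenerate_fit`) rather than silently regularized,
because a load estimate from such data is not meaningful under plain ML.
Separation is detected geometrically (the F ranges of successes and
failures do not interleave), which for a single covariate is exactly the
condition under which the MLE diverges. A Firth-penalized fit (Newton
iteration with the hat-diagonal score adjustment) is available behind
`firth = TRUE` for users who need finite estimates from separated
stage-specific subsets; it is off by default because the reference
analysis used plain ML.

Delta-method standard errors for $A_R$ and $B_R$ are offered via
`summary(fit, load_se = TRUE)` and are labelled as an extension:
conventional load tables print standard errors only for the logistic
coefficients.

### Stage-wise decomposition

`stagewise_fits()` fits copulation on all records, fertility on
copulated crosses, and development on fertile crosses. This conditional
factorization mirrors how the phenotypes are observed (a copulatory plug
can only be scored if the pair was watched; embryo development only if
embryos were laid) and makes the three fits independent given the data
splits, so the product of the three stage probabilities at a given F
equals the overall success probability — an identity the tests verify on
simulated data. A degenerate stage (e.g. copulation that never fails)
returns its error object in place, leaving the other stages usable.

Lines surviving to the stopping generation contribute exactly their
observed crosses; no survival-analysis censoring correction is applied,
because the per-cross binomial likelihood is already correct under
right-truncation of the line at its first failure. Block or experimenter
effects are not modelled: the design randomizes lines across
experimenters, and the reference model contains no block term.

## Lotka–Euler relative fitness

A female's schedule is the vector of adult-progeny counts per laying
interval: 0–6 h from pairing, then 8-h plates. Her contribution at
growth rate r is $w(r) = \sum_j m_j e^{-r x_j}$ with $x_j$ the interval
midpoint in hours. Design choices:

* **Age origin and placement.** Age is measured from initial pairing and
  each interval contributes at its midpoint — the least-biased placement
  for a piecewise-constant schedule when the within-interval laying
  profile is unknown. Development time to reproductive maturity is *not*
  added to x; a `maturation_offset` (hours) is available for sensitivity
  analysis, and lowering r with a positive offset is itself a property
  the tests check.
* **Normalization.** `solve_r()` finds the r at which the mean founder
  w equals 1, by bracketed root-finding (`uniroot`) after doubling the
  upper bracket; mean w is strictly decreasing in r, so the root is
  unique whenever mean total progeny exceeds 1. Tolerance is driven to
  machine precision, and the suite cross-checks against an independent
  Newton iteration using the analytic derivative. Non-growing founder
  sets (mean progeny ≤ 1) are an error unless `allow_nonpositive = TRUE`.
* **Zero and censored females.** A female with zero progeny has w = 0
  and stays in the estimate; exclusion is reserved for the explicit
  `censored` flag (mating failure, desiccation), which removes her from
  both normalization and comparison.

Because the founder broods are large (hundreds of progeny) and age is
counted from pairing, the solved r is large (≈ 1.3 h⁻¹ on the default
synthetic schedules) and w is dominated by the earliest intervals: an
8-h laying delay is nearly as damaging as losing the brood. This is a
real property of the estimator, not an artifact — it is why relative
fitness captures proliferative ability better than total offspring
number — but it means results are sensitive to the first interval's
counts.

`strain_heterogeneity_test()` applies the tie-corrected Kruskal–Wallis
test across the inbred lines of one founder. When every fitness value is
tied the textbook statistic is 0/0; the package returns H = 0, p = 1 by
continuity (no rank signal).

## What the synthetic-data generator emulates

`simulate_line_extinction()` draws, per line and generation, either one
overall success Bernoulli or the three sequential stage Bernoullis, each
with probability $\mathrm{logistic}(\beta_{0s} + \beta_{1s}
F_{\mathrm{par}}(g))$ — the exact generative model the analysis assumes,
so parameter recovery is a sharp test of the fitting code rather than of
model misspecification. An optional maternal-effect lethal event (rate
per line per generation) forces the development stage to fail
regardless of its own draw, reproducing the observed whole-brood-death
signature without within-brood segregation; it is modelled per line per
generation as the simplest mechanism with that signature. The paper-scale
default is 108 lines × ≤ 20 generations. `analytic_survival()` gives the
closed-form survival probability the Monte-Carlo fraction must converge
to; the suite checks agreement at 20 000 lines (and the acceptance tests
at 100 000) for overall, stage-heterogeneous and maternal-lethal
configurations.

`simulate_repro_schedules()` draws per-interval counts from a negative
binomial (dispersion configurable; `Inf` recovers Poisson) around a
hump-shaped founder mean schedule — default
(45, 110, 95, 60, 30, 12, 5, 2) adult progeny over eight intervals,
totalling ≈ 360, a realistic mated-female brood for these species —
with per-line multiplicative fitness effects, optional laying delays,
and optional maternal-lethal lines (all counts zero). Negative binomial
is the default because real brood counts are overdispersed relative to
Poisson. Six females per strain is the default assay size.

Random streams are split per line and per female (seeds derived from the
master seed by an integer mixing map), so enlarging an experiment never
perturbs the trajectories already generated — byte-identical
reproducibility under a fixed seed is asserted in the tests.

What the generator does **not** emulate: explicit loci, dominance
coefficients or purging dynamics (the generative model lives at the
phenotype/hazard level the regression fits); among-line heterogeneity in
the cross-success betas; experimenter blocks; and any correlation
between a line's extinction history and its reproductive schedule.
Passing tests therefore demonstrate that the estimators recover the
truth of *this* model at realistic sample sizes, not that the model is
correct for any particular real data set.

## Numerical and testing choices

* Likelihood-oracle tests compare the IRLS fit on ≤ 8-record toys with a
  Nelder–Mead maximization of the hand-written Bernoulli log-likelihood
  (agreement to $10^{-4}$).
* Parameter recovery and Wald-interval coverage use 100 replicates of
  the full 108 × 20 design at a strong-load truth (β₀ = 4.403,
  β₁ = −2.798); the mean recovered coefficients are required to sit
  within 3 empirical standard errors (the SD of the replicate estimates)
  of truth, and 95% Wald coverage within binomial error. The null
  calibration of the Wald test uses 200 replicates of n = 800; sizes
  were chosen so the whole suite runs in well under a minute while
  keeping the binomial error bars tight enough to be informative.
* The published 11-strain coefficient table ships in
  `inst/extdata/strain_load_coefficients.tsv`; conversion fidelity to
  its printed load values (3 decimals) and significance categories is
  asserted exactly. One known text-level caveat: the prose endpoint
  "69%" sometimes quoted for the strongest-load strain computes to 68.0%
  from the rounded table coefficients, so only the table values are
  treated as reproduction targets.

## Limitations

* Only the serial full-sib design is supported; there is no
  general-pedigree F computation.
* Strains are analyzed by pooling crosses; no per-line random effects.
* The fitness module models laying-window reproduction only (implicit
  survivorship 1 within the window) and is validated on synthetic
  schedules; published per-line fitness values from real schedules
  cannot be checked without the underlying raw data.
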