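---
title: "Measuring covariate balance with the Jensen-Shannon divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring covariate balance with the Jensen-Shannon divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jsdbalance)
```

## The problem

In a comparative clinical study, a covariate $C$ can confound the
treatment–outcome relationship whenever its distribution differs across the
treatment groups $T$. Balance — probabilistic independence of $T$ and $C$ —
is what randomization buys; in observational samples it has to be checked.
The usual checks each have failure modes: univariate summaries miss
multimodal structure, association tests track sample size as much as
imbalance, and the standardized difference score
$(\bar x_1 - \bar x_2)/\sqrt{(s_1^2 + s_2^2)/2}$ is blind to any imbalance
that leaves the means equal (unequal spread, mirrored skew, bimodality).

`jsdbalance` implements an information-theoretic alternative: the
Jensen–Shannon divergence (JSD) of the group-specific covariate
distributions, in bits.

## The statistic

Let $p_k(c_i)$ be the covariate distribution in group $k = 1, \dots, N$,
estimated by normalizing each group's column of counts, and let

$$\tilde p(c_i) = \frac{1}{N} \sum_{k=1}^N p_k(c_i)$$

be the *common distribution*, the unweighted mean of the group
distributions. The balance statistic is the average relative entropy
(Kullback–Leibler divergence) from the mixture to the groups:

$$\mathrm{JSD} = \frac{1}{N} \sum_{k=1}^N D\!\left(p_k(C) \,\Vert\, \tilde p(C)\right)
  = \sum_{k=1}^N \sum_{i=1}^M \frac{1}{N}\, p_k(c_i) \log_2
    \frac{p_k(c_i)}{\tilde p(c_i)}.$$

Key properties, each enforced by the test suite:

* **Finite and bounded.** The mixture support covers every group's support,
  so the JSD is always finite; with uniform weights it lies in
  $[0, \log_2 N]$, with 0 exactly at identical group distributions and
  $\log_2 N$ exactly at disjoint ones (`max_jsd()` reports the bound).
* **Sample-size invariant.** The statistic depends on group proportions
  only; rescaling any group's counts changes nothing. Group sample sizes do
  *not* weight the mixture — the mean is deliberately unweighted, so a
  small group's imbalance is not diluted by a large reference group.
* **Decomposable.** Because the JSD is a sum of expectations, the per-cell
  terms $(1/N)\, p_k(c_i) \log_2 (p_k(c_i)/\tilde p(c_i))$ decompose it
  additively. Column sums give group contributions $(1/N) D(p_k \| \tilde p)
  \ge 0$, row sums give covariate-level contributions (non-negative by the
  log-sum inequality), and the grand sum is the statistic. Individual cells
  may be negative: a negative cell flags a group under-represented at that
  level relative to the mixture.
* **Shape sensitive.** As a functional of the distributions themselves
  rather than their moments, the JSD detects spread, skew, and modality
  differences that leave a standardized difference score at zero.

An independent identity, $\mathrm{JSD} = H(\tilde p) - \frac{1}{N}\sum_k
H(p_k)$ with $H$ the Shannon entropy, is used throughout the tests as an
oracle against the definitional double sum.

`jsd_balance()` fits the statistic from a counts table or subject-level
data frame and stores the full decomposition; `tidy()`, `glance()`,
`group_contributions()`, `level_contributions()`, `rank_contributions()`
and `autoplot()` are views of the fitted object. The supporting kernel
(`entropy()`, `joint_entropy()`, `conditional_entropy()`,
`mutual_information()`, `relative_entropy()`, `jeffreys_divergence()`,
`jsd_divergence()`, `expected_code_length()`) is exported because the
balance statistic is best understood — and tested — through these
primitives.

## Conventions and numerical choices

* **Units.** Base-2 logarithms (bits) everywhere in reports; kernel
  functions take a `base` argument for nats or other units, but reported
  statistics are always bits.
* **Zero handling.** $0 \log 0 = 0$ throughout: a cell with zero count in
  one group contributes exactly 0 to that group's sum. A covariate level
  with zero count in *every* group carries no information (its mixture
  probability would be 0/0) and is dropped with a warning before fitting.
* **Infinite divergences.** `relative_entropy()` raises a domain error
  naming the offending label when the target has mass where the reference
  has none, rather than returning `Inf`: an infinite divergence means the
  requested balance comparison is undefined, and failing loudly beats
  propagating a sentinel. The JSD never hits this case, because each group
  is compared to a mixture that contains it.
* **Tolerances.** Probability vectors supplied directly must sum to 1
  within `1e-9`; vectors built from counts are normalized by the exact
  total, so the count path (the primary input path) is exact. Internal
  identities (additivity, chain rule, the entropy oracle) are tested at
  `1e-12`.
* **Display.** Reports round to 4 decimal places while totals are computed
  from unrounded cells; the text report says so, since rounded rows and
  columns need not sum to rounded totals.
* **Normalized JSD.** `jsd_balance()` also reports
  `jsd_bits / log2(n_groups)`. This ratio is a convenience rescaling to
  $[0, 1]$, clearly an extension beyond the statistic itself, and no
  threshold is attached to it: there is no principled cut-point for
  "acceptable" imbalance, and the reports say so rather than inventing
  one. What matters in practice is the covariate's potential to affect the
  outcome.

## Continuous covariates

A continuous covariate is binned histogram-style by `bin_groups()` before
the categorical machinery applies.

* Bin edges are computed **once from the pooled data** across all groups,
  so every group shares the same partition — per-group edges would make
  the group distributions incomparable.
* Default: 10 equal-width bins over the pooled min–max, intervals
  left-closed/right-open with the final interval closed so the maximum is
  included. Ten bins is the usual histogram-scale compromise between
  resolution and per-bin stability; there is no canonical count, and the
  choice is exposed.
* A `"quantile"` strategy uses pooled-sample quantiles as edges; duplicate
  edges from heavily tied data are collapsed with a warning (fewer bins
  result, rather than empty or ill-defined ones).
* Refining an equal-width partition can only increase the JSD (coarsening
  is a deterministic merge of categories, which never creates divergence);
  conversely, few bins can mask subtle shape differences. Per-bin
  proportions from small samples are noisy, so bin counts should respect
  the sample size.

For two *Gaussian* covariate distributions the JSD is computed exactly (to
quadrature accuracy) by `gaussian_jsd()`: trapezoid rule on an equally
spaced grid spanning $[\min\mu - 8\max\sigma,\ \max\mu + 8\max\sigma]$
with 20,001 points. The integrand is smooth, bounded, and decays with the
Gaussian tails, so this fixed deterministic grid is accurate well below
`1e-6`; the tests confirm agreement with a 4×-finer grid and invariance
under a common affine transform of both distributions.

`sdiff_jsd_curve()` traces JSD against the standardized difference for a
fixed SD ratio. The parameterization is a design choice the curve
description leaves open: group 1 is pinned at $\mathcal N(0, 1)$ and, for
each target standardized difference $d$, group 2 is
$\mathcal N(-d\sqrt{(1+\sigma_2^2)/2},\ \sigma_2)$, so the population
score of the pair equals $d$ exactly. This reproduces the expected
behavior: curves rise monotonically, saturate at $\log_2 2 = 1$ bit, and
with $\sigma_2 \ne 1$ start strictly above zero at $d = 0$ — the
spread-only imbalance a standardized difference score cannot see. Curves
use the *population* score (means and SDs of the specified Gaussians);
data are summarized with the *sample* score (`standardized_difference()`,
$(n-1)$ variances, combined SD $\sqrt{(s_1^2+s_2^2)/2}$ — the common
convention, since "combined estimate of standard deviation" admits
several). Both versions are exported.

## The synthetic-data generator

Two generators make every analysis path testable without external data:

* `simulate_multinomial_counts()` draws each group's level counts from a
  multinomial with stated probabilities — the idealization of a
  cross-classified cohort table. As group sizes grow, the JSD of the
  simulated table converges to the JSD of the generating distributions,
  which is how the package calibrates itself: the tests draw $10^6$
  subjects per group from the published glucose-by-deprivation
  distributions and recover the published 0.0144 bits within 0.001.
* `simulate_gaussian_groups()` draws subject-level continuous records from
  per-group Gaussian mixtures. Named presets cover the canonical shape
  scenarios: `location-shift` (the one case a standardized difference
  detects) and three matched-mean pairs it cannot —
  `scale-difference` ($\mathcal N(0,1)$ vs $\mathcal N(0,3)$),
  `skew-mirror` (a right-skewed mixture vs its reflection), and
  `bimodal-vs-unimodal` (an SD-matched normal vs a symmetric two-component
  mixture). Mixture parameters were fixed once to give means equal by
  construction and visibly different shapes.

Both record their seed and PRNG (Mersenne-Twister) so fixtures are
bit-reproducible. What the generators deliberately do **not** emulate:
missing-data mechanisms (readers exclude missing covariates complete-case,
with a logged count), measurement error, correlated multivariate
covariates, or the selection processes of a real cohort. Passing
tests therefore demonstrate the statistic's arithmetic and sampling
behavior, not robustness to real-data pathologies.

## Problem sizes in the test suite

Property-style invariants (decomposition additivity, non-negative margins,
sample-size invariance, the mixture-entropy oracle, Shannon's coding
bound, binning-refinement monotonicity) each run on 100 randomized
instances under fixed seeds, with tables up to 6×5 and continuous samples
of a few hundred observations; the binned-vs-quadrature comparison uses
$10^4$ draws per group and the multinomial recovery check $10^6$ per
group. These sizes were chosen to make Monte-Carlo error negligible
relative to the tested tolerances while keeping the whole suite fast.

## Known limitations

* Plug-in group proportions are increasingly variable in small samples;
  the JSD of a small table is a noisy estimate of the population JSD, and
  no bias correction or uncertainty interval is provided.
* Only univariate covariates are supported. A pre-formed
  cross-classification can be analyzed as a single categorical covariate,
  but the package does not construct multivariate binnings.
* No density estimation: the continuous route is binning plus exact
  Gaussian quadrature, nothing in between.
* No balance threshold is implemented, deliberately.
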