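---
title: "Methods: design, estimation and welfare analysis of a two-alternative DCE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design, estimation and welfare analysis of a two-alternative DCE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choiceval)
```

This vignette is the package's own account of the methods it implements:
the models, the conventions adopted where the methodology admits more than
one, the numerical choices, and what the simulation-based validation does
and does not demonstrate.

## The choice model

A discrete choice experiment presents each respondent with a series of
choice sets, each holding two unlabeled service profiles (A and B, no
opt-out). Under random utility theory the respondent picks the alternative
with the higher utility

$$U_{isj} = V_{isj} + \varepsilon_{isj}, \qquad
  V_{isj} = \beta^\top x_{isj},$$

with $\varepsilon$ i.i.d. standard type-I extreme value (Gumbel), which
gives the conditional logit probability
$P(j \mid s) = \exp(V_j) / \sum_k \exp(V_k)$.

Covariates use *analysis coding*: every non-reference level of a
categorical attribute contributes a 0/1 dummy (the reference, by
convention the usual-care level, encodes to all zeros), and the continuous
cost attribute contributes one numeric column holding the level's value in
euro per year. The cost attribute must be continuous for the
willingness-to-accept ratio $\beta_x / \beta_{cost}$ to be defined — coding
its four levels as three dummies would leave no unique money metric.

## Experimental design

The built-in attribute space (`pharmacy_dce_attributes()`) has four
three-level categorical attributes and one four-level cost attribute, a
$3^4 \times 4 = 324$-profile full factorial and $324 \cdot 323 / 2 =
52{,}326$ possible pairwise choice sets, far beyond what respondents can
answer. `search_fractional_design()` therefore:

1. selects a fraction of $2n$ distinct profiles by **Fedorov exchange**:
   from a random start, repeatedly swap the single in-design profile /
   candidate pair that most improves the D-criterion, until no swap
   improves it (iteration cap 10,000, configurable restarts keep the best
   of several local searches). Swaps are evaluated in closed form by the
   matrix determinant lemma on the intercept-augmented moment matrix, so a
   full search of the 324-profile space takes well under a second;
2. randomly pairs the fraction into $n$ two-alternative sets, re-drawing
   any pairing that would put two identical profiles in one set
   (`pairing = "independent"` instead selects two $n$-profile fractions by
   independent searches and pairs them index-wise);
3. randomly allocates sets to equal-sized questionnaire blocks — with the
   default 36 sets and 9 blocks, each respondent answers 4 sets.

**D-efficiency convention.** Efficiency of a candidate design is
$\left(\det \mathrm{cov}(X)\right)^{1/p}$ for the coded alternative matrix
$X$, relative to the same quantity for a perfectly level-balanced
orthogonal design. Two deliberate choices make this a well-behaved score:

* *all attributes are treated as factors* for design purposes. The design
  is constructed before any analysis metric is attached to the cost
  levels; treating cost as a numeric column at the design stage would
  reward piling observations onto the extreme cost levels and allow
  "efficiencies" above 1.
* *the intercept is profiled out* (covariance rather than raw moments).
  With raw dummy moments and no intercept, unbalanced level allocations
  can beat the balanced ideal. On the covariance scale the determinant of
  each attribute's dummy block is the product of its level frequencies
  (maximal at balance, by AM–GM), and the determinant of the whole matrix
  is bounded by the product of the blocks (Fischer's inequality), so the
  balanced orthogonal design is provably optimal and relative efficiency
  always lies in $(0, 1]$.

Under this convention random 72-profile fractions of the built-in space
score about 0.93 and the exchange search reliably reaches 0.999.

Dominated pairings (one alternative weakly better on every attribute) are
*not* filtered by default — orthogonal designs accept the occasional
illogical pairing in exchange for statistical efficiency — but
`avoid_dominated = TRUE` re-draws them where possible.

The sample-size helper implements the usual rule of thumb
$N > 500c/(ta)$ with $c$ the largest level count, $t$ tasks per
respondent, $a$ alternatives per task, returning
$\lceil 500c/(ta) \rceil$: at $c = 4, t = 4, a = 2$ this is 250
respondents.

## Estimation

`fit_clogit()` maximizes the conditional logit log-likelihood

$$\ell(\beta) = \sum_s \left[ V_{chosen} -
   \log \sum_j \exp(V_{sj}) \right]$$

by Newton–Raphson with the analytic gradient $X^\top(y - p)$ and observed
information, from a zero start. The log-likelihood is globally concave, so
the only numerical care needed is monotonicity (step halving) and a
stabilized log-sum-exp. Defaults: gradient-norm tolerance `1e-8`, at most
200 iterations. The covariance matrix is the inverse observed information
at the optimum (model-based, matching standard survey practice for this
design); respondents are the resampling clusters for the optional
percentile bootstrap (`bootstrap_coefficients()`, default 1,000
replications; replicates whose refit fails are skipped and counted, more
than 20% failures aborts).

Degenerate inputs are surfaced, never silently absorbed:

* a covariate that never differs within choice sets (or a collinear set of
  columns) is named in a rank error;
* **separation** — a covariate that perfectly predicts choice — is flagged
  both when an estimate diverges during iteration and, after numerical
  convergence, when any coefficient's within-set utility contribution
  spans more than ±15 on the Gumbel scale. The second check matters for
  wide-scaled covariates such as cost in euro: a separated fit can satisfy
  the gradient tolerance at a modest-looking coefficient while its choice
  probabilities sit within $3 \times 10^{-7}$ of 0/1.

Model fit is the likelihood-ratio chi-square $2(\ell_{full} - \ell_0)$
against the all-zero null (uniform choice), with degrees of freedom equal
to the coefficient count (9 for the built-in space). Group comparisons
(all / intervention / control) are separate fits on data filters, not
interaction terms, mirroring how such trials report per-arm preference
columns.

## Welfare analysis

* **Marginal WTA**: $\beta_x / \beta_{cost}$, in euro of annual NHS cost.
  The *plain* ratio is the default because, under a
  willingness-to-accept framing (cost borne by the payer, not the
  respondent), the cost coefficient is expected non-negative and published
  tables in this literature tabulate the plain ratio; the textbook
  $-\beta_x/\beta_{cost}$ is available via `negate = TRUE`. A cost
  coefficient that is exactly zero is an error (no silent infinities); one
  that is merely insignificant yields the ratio plus an attached caveat,
  since refusing to compute it would make the downstream CBA impossible
  while hiding the fragility would overstate it.
* **Krinsky–Robb intervals**: draw coefficient vectors from
  $N(\hat\beta, \hat V)$ (full covariance, not diagonal), recompute the
  ratio per draw, take percentile bounds. Draws with
  $|\beta_{cost}| < 10^{-12}$ are rejected and redrawn (count reported). A
  non-positive-semi-definite covariance is an error unless
  `repair_covariance = TRUE` projects it to the nearest PSD matrix.
* **Relative importance**: each attribute's utility range (max minus min
  level utility, reference at zero) over the sum of ranges, restricted by
  default to attributes with at least one coefficient significant at 0.05.
  Note that several conventions for "importance" circulate in the applied
  literature; shares computed by this range formula need not match figures
  derived by other weightings, and the package makes no attempt to
  reverse-engineer any alternative.
* **Compensating variation**:
  $(1/\beta_{cost})[\ln\sum_j e^{V_j^1} - \ln\sum_j e^{V_j^0}]$. With one
  alternative per state and cost-equal scenarios this reduces exactly to
  the summed marginal WTAs — an identity the test suite checks on random
  coefficient vectors.
* **Net benefit**: total WTA minus the incremental programme cost (a
  supplied constant, 88.80 euro/year for the built-in study; the package
  does not re-derive costing). Negative values pass through unclamped.

Euro values are rounded half-up to 2 decimals only at presentation;
internal arithmetic is unrounded.

## The simulator, and what the tests show

`simulate_choices()` generates data from *exactly* the data-generating
process the estimator assumes: each respondent is randomly assigned a
questionnaire block, utilities are linear in the analysis coding, and
errors are i.i.d. Gumbel via inverse-CDF ($-\ln(-\ln u)$) from a seeded
uniform stream, one per alternative per set. Defaults mirror the built-in
study's conditions: 78 intervention and 44 control respondents (each group
with its own true coefficient vector), 4 sets per respondent from a
36-set/9-block design — 976 alternative rows in total.
`inject_dominant_responders()` overwrites a chosen fraction of respondents
with strict single-attribute best-level behaviour in every informative set,
emulating non-trading respondents.

Validation performed by the test suite (problem sizes chosen to make
Monte-Carlo error small relative to the tolerances):

* closed-form likelihood values, likelihood concavity, and location
  invariance;
* MLE equality with a staged grid-search oracle on a 6-set instance (to
  $10^{-4}$) and with the stratified proportional-hazards partial
  likelihood (the construction classical survey software uses for this
  model);
* recovery of the built-in coefficient fixtures from 2,000 simulated
  respondents within 3 standard errors;
* likelihood-ratio type-I error $\approx 0.05$ over 500 simulated null
  cohorts of 60 respondents;
* empirical choice shares matching analytic logit probabilities at three
  utility gaps;
* dominance-screen recovery of an injected 14% dominant fraction against
  an exact analytic expectation (injected respondents plus
  $\sum (1/2)^{k}$ false positives over respondents with $k$ informative
  sets under uniform base choices);
* Krinsky–Robb bounds against a direct normal-ratio simulation, and CI
  width monotone in the covariance scale.

Because the simulator matches the model's assumptions by construction,
these tests validate the *implementation*, not the model: they say nothing
about scale heterogeneity, non-compensatory decision rules beyond strict
dominance, interviewer effects, or hypothetical bias in real survey data.

## Known limitations

* Only two-alternative, unlabeled, forced-choice designs (no opt-out), as
  in the built-in study.
* No random-parameters (mixed) logit, latent-class or hierarchical Bayes
  estimators; preference heterogeneity beyond the group split is not
  modelled.
* Bayesian (prior-informed) D-efficient design criteria are out of scope;
  the search optimizes the main-effects linear D-criterion.
* WTA ratios inherit the fragility of a small or insignificant cost
  coefficient; the package reports this as a caveat rather than refusing
  the computation, and the Krinsky–Robb intervals make the resulting
  uncertainty visible (they are typically very wide in that regime).
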