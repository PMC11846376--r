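---
title: "Data-driven subgroup thresholds from honest causal forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven subgroup thresholds from honest causal forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootsplit)
```

## The problem

Two-arm randomised trials estimate an average treatment effect, but a null
average can hide subpopulations that benefit and subpopulations that are
harmed. Classical subgroup analysis tests one treatment-by-covariate
interaction at a time and, for a continuous covariate, a significant
interaction still does not say *where* to draw a clinically usable
boundary. `rootsplit` implements three escalating analyses of
heterogeneous treatment effects (HTE) for trials with a binary outcome —
a univariable interaction screen, a strong-hierarchy interaction lasso,
and an honest causal forest — and a procedure that converts the forest
into an actionable two-subgroup partition: tally the forest's root splits,
take the modal variable, average its thresholds, and estimate the group
average treatment effect (GATE) on each side with doubly robust scores.

The motivating application is a critical-care trial in which the effect of
early vasopressin on 28-day survival varied with baseline serum potassium;
the package's synthetic generator is calibrated to that setting and is used
throughout for validation.

## Models and procedures

### Univariable screen

For each candidate modifier $X_k$ the screen fits
$\operatorname{logit} E[Y \mid W, X_k] = \beta_0 + \beta_1 W + \beta_2 X_k
+ \beta_3 W X_k$ by maximum likelihood and reports Wald inference on
$\beta_3$, with the Bonferroni threshold $\alpha / K$ and
Benjamini–Hochberg flags for volcano-plot colouring. The displayed model
includes an intercept even though compact presentations of this model
often omit it. Separation is detected and reported as a non-converged
sentinel (p = 1, infinite CI) rather than a crash, so simulation power
summaries are not contaminated by spuriously tiny p-values.

### Strong-hierarchy interaction lasso

The data-adaptive middle ground fits all treatment interactions jointly
with a penalty imposing the strong hierarchy $\beta_{3,k} \ne 0
\Rightarrow \beta_{2,k} \ne 0 \text{ and } \beta_1 \ne 0$. The hierarchy
is built in by a latent overlapping-group parameterisation: each
interaction coefficient exists only inside a three-member group that also
carries copies of its two main effects, so the optimiser cannot activate
an interaction without activating the mains. Groups carry
$\sqrt{\text{size}}$ weights; we found unit weights (a tempting
simplification) underpenalise the three-member groups enough that
cross-validation keeps noise interactions in almost half of pure-noise
fits. The objective is minimised by monotone proximal gradient descent
with backtracking, warm-started along a geometric 50-value path from
$\lambda_{\max}$ (all groups zero) to $10^{-3}\lambda_{\max}$;
convergence is declared when the relative objective change falls below
$10^{-7}$. The penalty is chosen by 5-fold cross-validation, stratified
by outcome, minimising held-out binomial deviance; the deviance minimiser
(not the 1-SE rule) is used because with the calibrated effect size the
1-SE rule occasionally drops the true interaction, while the minimiser
retains it in every replicate. The cost of that choice is imperfect
sparsity under the null: pure-noise fits keep at least one interaction
roughly a quarter of the time. Post-selection "significance" is a naive
Wald test from an unpenalised refit on the selected support, labelled as
such in the output; selective inference is out of scope.

### Honest causal forest

The forest estimates the conditional average treatment effect
$\tau(x) = E[Y(1) - Y(0) \mid X = x]$ under the partially linear model
$E[Y \mid W, X] = m(X) + W\,\tau(X)$. The nuisances $p(X) = E[W \mid X]$
and $m(X) = E[Y \mid X]$ are random-forest regressions (ranger) whose
out-of-bag predictions define the residuals $W - \hat p(X)$ and
$Y - \hat m(X)$; in a randomised design the propensity can instead be
fixed at the known randomisation probability. The nuisance forests use a
minimum leaf size of $\max(5, n/25)$: with the default deep trees the
out-of-bag estimate of a binary outcome's conditional mean is noisier
than the constant predictor, and smoothing halves that error.

Each of $B$ causal trees is grown on a without-replacement subsample
(fraction 0.5), split half/half into a grow set and an estimate set
(honesty): the grow half chooses splits, the estimate half populates the
leaves, and leaves left empty of estimate rows are collapsed into their
siblings. A split maximises the squared difference in leaf means
$n_L n_R (\bar\rho_L - \bar\rho_R)^2$ of the one-step pseudo-outcomes
$\rho_i = (W_i - \hat p_i)\{Y_i - \hat m_i - (W_i - \hat p_i)\hat\tau_P\}
/ \overline{(W - \hat p)^2}$, where $\hat\tau_P$ is the parent node's
residual-ratio effect estimate: a child's mean of $\rho$ estimates how far
its treatment effect deviates from the parent's. We deliberately did not
use the child-level ratio estimate
$\sum w_r y_r / \sum w_r^2$ inside the criterion: its denominator
collapses for small children, and in calibration runs the root-split
threshold distribution grew a heavy tail of extreme splits that shifted
the mean threshold by ~0.4 units while leaving the median untouched. For
the same reason each child must contain at least 10% of its parent's rows
(and at least `min_node_size = 5` rows, with both arms represented).
Candidate thresholds are midpoints between consecutive sorted values;
ties in the criterion resolve to the lowest variable index and threshold,
making the grower reproducible and directly comparable to a brute-force
oracle in the tests.

The CATE at $x$ is the forest-weighted residual ratio with weights
$\alpha_i(x)$ counting how often row $i$ shares an (estimate-half) leaf
with $x$; out-of-bag CATEs for training rows use only trees whose
subsample excluded the row. Defaults: $B = 2000$ for single-dataset
analyses and 500 inside simulations, `mtry` $= \min(K, \lceil\sqrt K\rceil
+ 3)$, all exposed and logged.

### Omnibus heterogeneity test

With $\bar\tau$ the mean out-of-bag CATE, the outcome residuals are
regressed (no intercept) on $A_i = \bar\tau (W_i - \hat p_i)$ and
$D_i = (\hat\tau_i - \bar\tau)(W_i - \hat p_i)$. The coefficient on $D$
is the differential forest prediction (DFP): values near 1 indicate the
forest's heterogeneity is well calibrated, and a one-sided test of
DFP > 0 is an omnibus test for the presence of heterogeneity. The DFP
standard error is the HC3 value scaled by $\sqrt 2$: $D$ is built from
out-of-bag forest weights that are close to symmetric in row pairs, so
the score $\sum_i D_i (Y_i - \hat m_i)$ is a symmetric quadratic form in
the outcome residuals and its variance is about double what the
fixed-regressor formula reports. Simulation under the homogeneous null
(500 replicates of $n = 1000$, $B = 250$) puts the corrected test's
rejection rate at 6% at nominal 5%, inside the 3–8% band the package
tests enforce; without the correction it is ~14%.

### Root-split subgroups and GATEs

Each tree's root split is the single best effect-separating cut on its
subsample, so the distribution of root splits across the forest measures
which variable, and which cut point, most consistently separates
treatment responders. The summary tallies root counts per variable
(one-hot levels fold back onto their parent categorical), takes the modal
variable (ties flagged, broken towards the lower column index), and
averages its thresholds — the mean, not the median, defines the
procedure, though a median option exists for robustness checks.
Thresholds learned on standardised covariates are mapped back to raw
units via stored centring metadata before averaging, so the reported cut
point is in the covariate's clinical units.

The population is then partitioned at the threshold (`low`: value at or
below; `high`: strictly above) and each side's GATE is the mean of the
doubly robust AIPW scores
$\Gamma_i = \hat\tau_i + \frac{W_i - \hat p_i}{\hat p_i (1 - \hat p_i)}
\{Y_i - \hat m_i - (W_i - \hat p_i)\hat\tau_i\}$, with standard error
$\mathrm{sd}(\Gamma)/\sqrt{n}$ over the subset. Because the same data fit
the forest and define the scores, these intervals can understate
uncertainty; every GATE printout carries that caveat, and the intervals
are for hypothesis generation, not confirmation. Under the homogeneous
null the whole-population interval covered zero in 96.8% of 500
simulated trials.

### Missing data and covariate screening

The preprocessing mirrors standard trial practice: covariates missing in
at least 30% of participants are dropped (strictly-below-30% kept);
among pairs with pairwise-complete Pearson $|r| > 0.7$ the member with
more missingness (then a derived-score flag, then the later column) is
dropped, visiting pairs greedily by decreasing $|r|$; categoricals are
one-hot encoded keeping all levels (downstream models are penalised or
tree-based; the unpenalised screen re-encodes with a reference level);
continuous covariates are centred and scaled by the sample SD with the
original mean/SD stored for threshold back-transformation. Four
missing-data strategies are provided: iterative random-forest imputation
(variables visited by increasing missingness, refitted each sweep,
stopped the first time the summed normalised discrepancy between sweeps
rises, returning the previous sweep; 100 trees, `mtry`
$=\lceil\sqrt p\rceil$), mean/mode imputation, complete-case deletion,
and inverse-probability-of-completeness weighting (logistic model of the
completeness indicator on treatment, outcome and fully observed
covariates; probabilities below 0.01 are truncated at the 1st percentile
with a recorded note; weights propagate to the univariable screen but not
the lasso, which does not accept weights).

## The synthetic trial generator

Because the motivating trial's data cannot be redistributed, validation
rests on a calibrated generator: $W \sim \text{Bernoulli}(0.5)$, a
prognostic $X_1 \sim N(0,1)$, an effect modifier
$X_2 \sim N(4.58, 0.937^2)$ in mmol/L (matching the observed maximum
serum potassium distribution), subgroup membership $S = 1\{X_2 > 4.68\}$
(strict inequality), and
$Y \sim \text{Bernoulli}(\text{expit}(\beta_0 + 0.5 X_1 + \beta_W W +
\beta_{WS} W S))$. `calibrate_dgp()` solves $(\beta_0, \beta_W,
\beta_{WS})$ so that control-arm survival is 72.5% and the subgroup risk
differences are +0.069 ($S=0$) and −0.257 ($S=1$); because $S$ does not
enter the control arm, the three targets decouple into three univariate
root-finding problems on the quadrature-integrated survival curve, making
calibration deterministic. The prognostic strength 0.5 log-odds per SD is
a package choice (exposed in the config): strong enough that nuisance
estimation matters, weak enough not to dominate the outcome. Re-simulating
$10^6$ participants reproduces each target within 0.005 (tested).

A richer `generate_vanishlike()` mode adds tens of mixed-type covariates,
MCAR/MAR missingness and correlated pairs to exercise the preprocessing
path. What the generator does *not* emulate: longitudinal daily
measurements, a competing-risk composite outcome, informative (MNAR)
missingness, and real covariate dependence structures beyond pairwise
correlation — so green tests here say the estimators work under the
stated sampling model, not that they are robust to everything a real
trial table contains.

## The simulation study

`run_simulation()` repeats, per replicate: generate a trial of $n = 1000$;
fit the causal forest ($B = 500$) and extract the modal root split and its
mean threshold; fit the univariable interaction model with continuous
$X_2$ and with $X_2$ dichotomised at a hypothesised clinical value of 5.4
(deliberately different from the true 4.68); and run the hierarchical
lasso in both codings with the refit Wald test. Replicate seeds are drawn
up front from the root seed, so results are identical under serial or
parallel execution. The default harness runs 100 replicates (the
full-scale design of 1000 is a parameter away); percentages carry binomial
Monte-Carlo standard errors. The aggregate report includes the modal
identification rate, the mean/SD/MSE (population form, vs the true 4.68)
and empirical 95% range of per-replicate mean thresholds, and the four
comparator powers at the 5% level.

Problem sizes used by the package's own validation: the replication run
is 100 replicates at $n = 1000$, $B = 500$; the null-calibration
properties use 500 replicates at $n = 1000$ with $B = 250$ and 200-tree
nuisances; property fixtures (split-oracle equivalence, honesty audits)
use 36–40-row datasets where exhaustive enumeration is feasible.

## Numerical choices and degenerate inputs

* Subgroup membership and dichotomisation use strict ">"; a value exactly
  at the threshold belongs to the low group.
* Propensities are clipped to [0.01, 0.99] so doubly robust score
  denominators are bounded; clipped rows are flagged.
* A node whose residual denominator vanishes, or with no admissible
  split, becomes a leaf; a forest of stumps yields an all-zero importance
  vector and a defined "no splits" root summary.
* Split-criterion ties break to the lowest variable index, then lowest
  threshold; fold assignment, subsampling and tree growth are all
  deterministic functions of recorded seeds (Mersenne–Twister on the R
  side, a seeded 64-bit generator with platform-stable integer draws in
  the tree grower).
* Constant CATE vectors make the calibration regressor degenerate; the
  test returns a defined "no heterogeneity detected" outcome.
* Zero-variance continuous columns are dropped with a recorded note; an
  empty design after filtering is an explicit error.

## Known limitations

* The forest machinery is a faithful but simplified honest causal forest:
  no gradient-tree-boosting-style split approximations, no
  bootstrap-of-little-bags variance estimates, hence no pointwise CATE
  confidence bands; the CATE distribution is exported for histograms
  instead.
* Root-split threshold recovery is noisier than the reference
  implementation it emulates (cross-replicate SD ≈ 0.10 vs 0.0725 at the
  same design), a direct cost of the simpler splitting statistic.
* GATE intervals inherit the "same data twice" optimism discussed above.
* The lasso's post-selection p-values are non-selective by construction.
* Survival outcomes, competing risks, clustering and longitudinal
  covariates are out of scope.
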