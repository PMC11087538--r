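---
title: "Multimodal trajectory mixtures: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal trajectory mixtures: model, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`mtm` stratifies subjects by the *shape* of their multimodal trajectories
rather than by a snapshot. Each subject $i$ contributes a variable-length
sequence of biomarker states $z^i_{1:T}$ (e.g. grey-matter density and
amyloid burden, dimension $d$) and cognitive observations $x^i_{1:T}$
(dimension $\ell$), one pair per visit. The cohort is modeled as an i.i.d.
sample from a mixture of $n_c$ linear Gaussian state-space models: a
categorical cluster indicator with weights $\pi_c$ selects a component, and
under component $c$

$$
p(x_{1:T}, z_{1:T} \mid c) \;=\;
\eta_d(z_1;\, m_c, S_c)\,
\prod_{t=2}^{T} \eta_d(z_t;\, z_{t-1}A_c, \Gamma_c)\,
\prod_{t=1}^{T} \eta_\ell(x_t;\, z_t H_c, \Lambda_c),
$$

with $\eta_k$ the $k$-dimensional Gaussian density. Row-vector convention
throughout: $A_c$ ($d \times d$) maps the previous state row vector to the
next-state mean, and $H_c$ ($d \times \ell$) reads the cognitive mean out
of the current state. The interpretation is causal in spirit: biomarker
dynamics drive progression, and cognitive scores are inexpensive, noisy
read-outs of the latent biological stage. Visits are equally spaced indices
$t = 1..T$ (assessments roughly two years apart in the motivating cohorts);
calendar time is deliberately not modeled, as the dynamics are first-order
and discrete.

Two assumptions matter in practice. First, *training* requires complete
trajectories — both modalities observed at every visit — because states are
treated as data, not inferred latents (the "privileged information"
setting: biomarkers are available in research cohorts but often missing in
the clinic). Second, at *test* time any cell may be missing: because the
joint distribution of a trajectory under one component is Gaussian, missing
coordinates are integrated out exactly.

## Estimation

`mtm_fit()` runs hard-assignment EM. The E-step assigns each subject to
$\arg\max_c \log \pi_c + \log p(x^i, z^i \mid c)$ (ties to the lowest
index, deterministically); the M-step refits each component in closed form:
$\pi_c$ as the cluster share, $(m_c, S_c)$ as mean/covariance of first
states, $A_c$ by least squares over within-cluster consecutive state pairs
with $\Gamma_c$ the residual covariance (the joint conditional MLE), and
$(H_c, \Lambda_c)$ likewise over all within-cluster visits. The objective
$J = \sum_i \log \pi_{c^i} + \log p(x^i, z^i \mid c^i)$ is a coordinate
ascent, so it is non-decreasing — the test suite asserts this on every
restart of every fit.

Because hard EM is sensitive to initialization, each fit runs
`n_restarts = 10` k-means seedings on per-trajectory summary vectors
(concatenated mean state and mean observation), one RNG seed per restart,
and keeps the restart with the highest final objective. Convergence is
declared on a relative objective change below `tol = 1e-6` or a label
fixed point; `max_iter = 200` is a safety net, not a tuning knob. These
values are configurable in `mtm_fit_config()`; the defaults were chosen
once as ordinary values for a coordinate-ascent mixture fit of this size.

Numerical safeguards:

* every estimated covariance is symmetrized and eigenvalue-floored at
  `1e-6 * trace/dim` (plus a `1e-10` absolute guard so that pathological
  inputs such as a cluster of identical trajectories still produce finite,
  positive-definite output);
* clusters that fall below `d + l + 1` members mid-EM are refilled with the
  trajectories farthest from the donor cluster's centroid; if refilling is
  impossible the restart is dropped with a warning;
* rank-deficient regressions fall back to the Moore–Penrose pseudo-inverse
  with a warning;
* all mixture aggregation (posteriors, BIC likelihood) is done in the log
  domain via log-sum-exp, so posteriors stay finite for log-likelihood
  spreads of thousands of units.

The E-step evaluates complete-data likelihoods in batch: trajectories are
grouped by length, the joint Gaussian moments of a length-$T$ trajectory
under each component are built once, and one Cholesky factorization per
(component, length) scores the whole group. `complete_data_loglik()`
retains the factored per-visit recursion as the reference implementation;
the equality of the two paths is a unit test, and both are validated
against an independently constructed brute-force joint-Gaussian oracle.

## Missing data and the Kalman recursion

`marginal_loglik()` computes $\log p(\text{observed cells} \mid c)$ exactly
via sequential prediction/update: at each visit the joint Gaussian of
$(z_t, x_t)$ given the past has mean $(\mu_t, \mu_t H)$ and covariance
blocks $(P_t, P_t H;\; H^\top P_t, H^\top P_t H + \Lambda)$; the observed
slice — any subset of the $d + \ell$ coordinates — contributes its
predictive log-density, and the state belief is conditioned on it in a
single blockwise update (observed states are conditioned on like any other
coordinate, which is equivalent to clamping and keeps one code path).
Missingness is treated as ignorable (MAR); masks select coordinates but
never enter the likelihood. On complete data the recursion reproduces the
factored likelihood to machine precision, and under arbitrary masks it
matches the brute-force marginal of the full $T(d+\ell)$-dimensional joint
to $10^{-7}$ over hundreds of randomized cases.

## Model selection, cross-validation, harmonization

`mtm_bic()` uses the *soft* mixture likelihood
$\sum_i \log \sum_c \pi_c\, p_i(c)$ — the standard BIC argument, rather
than the hard-assignment objective — with $N$ equal to the number of
trajectories (the i.i.d. unit) and
$k = (n_c - 1) + n_c\,[d + d(d{+}1)/2 + d^2 + d(d{+}1)/2 + d\ell +
\ell(\ell{+}1)/2]$ free parameters.

`cross_validate()` runs $k$-fold CV (default 10), stratified by diagnosis
when labels exist so that small folds retain all outcome classes, with a
seed-controlled deterministic split. Mixture labels are arbitrary per fold,
so each fold model is *harmonized*: clusters are labeled "A", "B", ... in
ascending order of their training-set AD-diagnosis fraction (ties: pMCI
fraction, then raw index). Every subject is predicted exactly once, by the
unique fold model that did not train on it — the index in particular is
always computed on held-out data. A stability histogram counts, per
subject, how many of the $k-1$ models trained on it agree with its
held-out label. When no diagnoses exist, the fallback ordering uses the
cluster mean of each member's mean observation score, descending by
default (under the convention that higher cognitive scores are healthier);
the direction is configurable because score polarity is cohort-specific.

The cognitive health index is $M = \log p(\text{available data} \mid
c = \text{"A"})$, defined up to an additive constant. Raw $M$ is
length-dependent (every visit adds likelihood terms), so the package
reports both raw and per-visit-normalized variants rather than silently
choosing one.

## The synthetic cohort generator

`make_cohort()` exists so the whole pipeline is testable without
access-restricted clinical data. The default preset mirrors the structure
of the motivating research cohort: 571 subjects, trajectory lengths 2/3/4
in proportions 337/194/40, $d = 2$ biomarker states, $\ell = 4$ cognitive
scores, 4 clusters with equal weights. Cluster state means are placed along
a severity axis (direction alternating in sign across coordinates, as
grey matter falls while amyloid rises) with adjacent clusters
`separation = 5` SD apart — a line rather than a simplex, since $n_c = 4$
points cannot form a simplex in $d = 2$ dimensions, and a monotone severity
gradient is the clinically meaningful geometry. The healthiest cluster sits
farthest from the origin and dynamics are contractive
($A_c = \rho_c I$ plus a small alternating coupling, $\rho_c$ falling from
0.98 to 0.80 with severity; spectral radius $< 1$ always), so severer
clusters decay faster toward an end-stage attractor. Emissions share a base
read-out matrix (one score inverted, mimicking scales where higher is
worse) plus a small cluster perturbation. Noise defaults
(`state_noise = 1`, `trans_noise = 0.25`, `obs_noise = 0.25`) keep
transition and emission noise well below the between-cluster separation, as
in the well-separated regime the method targets.

Diagnoses are drawn per subject from the *true cluster's* categorical
distribution over CN/sMCI/pMCI/AD, with AD mass rising monotonically with
severity (2% to 60% by default). This makes "clusters explain diagnosis"
recoverable by construction, but imperfectly so — matching the real-world
situation where cluster membership and clinical labels are correlated but
far from identical.

What the generator does *not* emulate: calibrated biomarker units
(centiloid scales), covariate effects such as age and sex, informative
missingness, irregular visit spacing, and measurement-batch effects.
Passing recovery tests on these cohorts therefore demonstrates the
correctness and stability of the estimation machinery under the model's
own assumptions — not performance on real clinical data.

## Problem sizes in the shipped checks

The test suite and the acceptance script work at the preset's native scale
(571 subjects, 10-fold CV, 10 restarts) for the headline recovery checks,
240 subjects for the BIC selection study (10 replicates over candidates
1–6), and 200–500 subjects for the remaining simulation checks; these sizes
were chosen so that each check is decisive (Monte-Carlo error well below
the asserted margins) while the whole suite stays fast on a single CPU.

## Known limitations

* Dynamics and emissions are linear and time-homogeneous; nonlinear
  read-outs are out of scope.
* Training cannot use partially observed trajectories; subjects with any
  missing training cell are rejected (by design, with a per-subject
  report), which discards data a latent-state EM could exploit.
* The AD-fraction harmonization needs diagnosis labels on the training
  folds; the observation-score fallback depends on a configurable polarity
  convention.
* Hard assignment underestimates assignment uncertainty near cluster
  boundaries; the reported posterior is conditional on the fitted model
  and inherits its overconfidence.
* BIC counts parameters as if all trajectories had equal information;
  with very unbalanced length distributions this is an approximation.
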