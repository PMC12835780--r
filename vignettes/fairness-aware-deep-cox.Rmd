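---
title: "Fairness-aware deep Cox models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fairness-aware deep Cox models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Risk models trained on registry-scale survival data are dominated by the
majority demographic group. A model that discriminates well on average can
still rank one group's patients poorly against the rest of the cohort, or
systematically under-estimate their absolute risk — and in clinical use
those errors translate into unequal care. `fairsurv` provides a deep Cox
proportional hazards toolkit in which the training objective, not the data
or the predictions, carries the fairness intervention, together with the
metric suite needed to see whether the intervention worked: cross-group and
within-group concordance, IPCW-weighted calibration scores, and
risk-stratified survival audits.

Throughout, the sensitive attribute (the group label) is *never* a
predictor. It enters only the training objectives and the evaluation
metrics.

## Model and objectives

The model is a proportional-hazards regression whose log-hazard is a
feed-forward network $f_\theta(x)$: subject $i$ has hazard
$h_i(t) = h_0(t)\,e^{f_\theta(x_i)}$. The network is deliberately small and
unregularised by architecture: an input linear layer to width 32, four
hidden layers of width 32 with SELU activations (self-normalising, so no
batch normalisation), and a linear projection to one scalar. Setting
`hidden_layers = 0` with a linear activation collapses it to a classical
linear Cox predictor, which the tests use to verify that training recovers
a known generative linear predictor.

Three objectives share one training loop (`dcph()`):

* **baseline** — the mean negative Cox partial log-likelihood over
  observed events,
  $L = -\tfrac1{n_E}\sum_{i:\delta_i=1}\big[f_\theta(x_i) -
  \log\sum_{j \in R(o_i)} e^{f_\theta(x_j)}\big]$,
  with risk sets $R(t)=\{j : o_j \ge t\}$ and Breslow handling of tied
  event times (tied events share one risk set, consistent with the
  Breslow baseline-hazard estimator used downstream).
* **fair** — baseline plus $\lambda \sum_k (\bar f_k - \bar f)^2$, the
  squared deviation of each group's mean predicted log-hazard from the
  overall mean. The penalty discourages the network from separating
  groups in mean predicted risk; $\lambda$ defaults to 1, the weight
  implicit in writing the penalty as a plain additive term.
* **groupdro** — the worst case over groups of the group-restricted
  negative partial log-likelihood: group $k$'s term sums only its own
  events (normalised by that group's event count) while the risk sets
  still span the whole cohort, and an augmented group $k=0$ — the
  unrestricted full-cohort loss — is always in the running, so the
  worst-case objective can never fall below the baseline objective and
  global fit cannot silently collapse.

### Stochastic training and risk sets

Risk sets are defined over the entire cohort, but stochastic training
works on mini-batches of 128. The package follows standard deep-Cox
practice: *within-batch* risk sets during gradient steps, *full-cohort*
risk sets (within the cohort being scored) for every reported, validation
or post-hoc quantity. Both paths share one implementation; the
discrepancy vanishes as the batch size grows and is part of the noise the
early-stopping criterion sees. Mini-batches that happen to contain no
events are skipped and counted, never fatal.

Optimisation is SGD with momentum 0.9, initial learning rate 0.01 decayed
by 0.1 every 5 epochs, weight decay 0.001, at most 100 epochs, and early
stopping with patience 5 on the validation objective (the model's *own*
objective evaluated on the held-out split), restoring the
best-validation weights. Layer weights initialise uniformly on
$\pm 1/\sqrt{\mathrm{fan~in}}$ under the run seed; given a seed, training
is exactly reproducible.

### The group-DRO update rule

The worst-case objective says nothing about how to step. Two rules are
implemented:

* `dro_rule = "eg"` (default): exponentiated-gradient weights over the
  group terms, $q_k \propto q_k e^{\eta L_k}$ with step $\eta = 0.1$,
  gradient $\sum_k q_k \nabla L_k$ — the canonical online group-DRO
  update.
* `dro_rule = "hardmax"`: the gradient flows through the single worst
  group's term each batch.

The hard max was the first candidate, but at desk scale it is
demonstrably the wrong default: with a 2% group and batch size 128, a
group's per-batch term rests on one or two events, the argmax chases
sampling noise, and in our simulations the cross-group concordance gap
*widened* relative to baseline in 9 of 10 seeds. The smoothed weights
average that noise while preserving the worst-case focus; with them the
gap narrows in the majority of seeds and the planted group-2 deficit
shrinks in all of them. The reported and validation objective is the
worst-case (max) value under either rule. Groups absent from a batch
contribute nothing that step; `stratify_batches_by_group = TRUE`
interleaves groups into every batch for cohorts where small-group
starvation is a concern (off by default).

## Breslow baseline hazard and absolute risk

After training, absolute survival needs the baseline hazard the partial
likelihood eliminated. At each unique event time,
$h_0(t_j) = d_j / \sum_{l \in R(t_j)} e^{f_\theta(x_l)}$, and
$S_i(t) = \exp\{-H_0(t)\, e^{f_\theta(x_i)}\}$ with $H_0$ the
right-continuous cumulative sum. Conventions the literature leaves
implicit, fixed here: subjects censored exactly at $t_j$ remain in
$R(t_j)$; tied events share one increment; survival curves are
right-continuous step functions. With constant scores the estimator *is*
Nelson–Aalen, and a global score shift moves the increments and the
exponent in exactly cancelling directions — both identities are asserted
numerically in the tests.

## The fairness metric suite

Comparable pairs are $(i,j)$ with $o_i < o_j$ and $\delta_i = 1$.
Harrell's C uses all of them; the **within-group** C-index of group $k$
keeps pairs entirely inside $k$; the **cross-group** C-index keeps pairs
where exactly one member is in $k$, which is the quantity that detects a
group being mis-ranked *against the rest of the cohort*. Score ties count
one half. Every variant is computed from one pass that tallies pairs,
concordances and ties in a $K \times K$ matrix indexed by the groups of
the two pair members; the identity
$|\mathrm{all}| = \sum_k |\Omega_k| + \tfrac12 \sum_k |\Omega_k^{cross}|$
is a test invariant. A group with no events has an empty pair set and
reports a defined-missing `NA` with a reason, never a silent `NaN`.

The **integrated Brier score** reweights squared prediction error for
censoring with IPCW weights
$w_i(t) = \delta_i 1(o_i \le t)/\hat G(o_i^-) + 1(o_i > t)/\hat G(t)$,
where $\hat G$ is the Kaplan–Meier estimate of the censoring
distribution fitted on the *full* cohort (left-limit convention at the
subject's own time). The **integrated calibration index** compares each
predicted $S_i(t)$ with a calibrated value from a loess (degree 1, span
0.75) of the IPCW-weighted status indicators on the predicted
probabilities, clipped to $[0,1]$; when predictions at a time are
degenerate the calibrated value falls back to the IPCW-weighted
empirical survival. Both integrate over $(0,\tau]$ by the trapezoid rule
— the Brier score on the curve's stored grid, the ICI on event-time
deciles to bound smoother cost — and divide by $\tau$. The default
horizon is the 99th percentile of follow-up rather than the maximum,
avoiding the unstable tail where $\hat G$ is built on a handful of
subjects; terms with $\hat G = 0$ are dropped and counted. Smoothing is
per time point; pooling over time would be the other defensible reading,
and the choice is surfaced here because the difference is not always
negligible.

Confidence intervals are percentile bootstrap over subjects (default
1000 replicates, minimum 100), one resampling pass serving the whole
report; replicates in which a group vanishes are skipped per metric and
counted, with a warning beyond 10%.

## Risk-stratified audit

`stratify()` cuts predicted risk at quantiles `(q_low, q_high)`; within
each stratum, `audit()` compares the groups' observed Kaplan–Meier
curves with two-sided pairwise log-rank tests. Under a fair model,
subjects placed in the same predicted-risk category should die at
similar rates regardless of group; a group whose curve sits
significantly below its stratum peers is having its risk
under-estimated. The default cutpoints are `(0.25, 0.75)` — high = top
25%, mid = middle half, low = bottom 25%; the alternative
top-25/25–50/bottom-50 scheme used in some presentations of this audit
is available as `cutpoints = c(0.50, 0.75)`. Both are supported because
the two conventions coexist in the applied literature and neither is
canonical. P-values are reported raw by default with an optional
Bonferroni flag, matching how such audits are usually read.

Boundary ties are broken by stable subject order; a cohort whose scores
are all identical is assigned wholly to the middle stratum with a
warning rather than split arbitrarily.

## The synthetic cohort generator

Real registry cohorts of this kind are license-restricted, so the
package ships a generator (`simulate_cohort()`) whose default
configuration (`default_ncdb_like()`) emulates the statistical structure
such an analysis faces:

* five groups with strongly imbalanced proportions
  (78.5/13.2/4.5/2.0/1.9 percent, renormalised because the published
  percentages sum to 100.1);
* per-group Weibull baselines (shape 1.2, scale 180 months,
  administrative censoring at 240 months, exponential censoring with
  rate 1/150 — roughly 55–60% censored, a plausible post-treatment
  overall-survival regime);
* ten standard-normal covariates with log-hazard coefficients between
  −0.4 and 0.5;
* a group-2 log hazard ratio of +0.5 (mortality HR ≈ 1.65, in the range
  reported for the disadvantaged group in this literature) and mild
  protective effects (−0.1 to −0.15) for groups 3–5;
* a *weak* covariate channel: groups shift the means of the first two
  covariates by at most 0.2 SD, so the predictors encode group
  membership only partially;
* a standard-normal covariate *withheld* from the design matrix that
  multiplies group 2's hazard by $e^{z}$ — one SD of unmeasured severity
  per unit log-hazard.

The last two choices are the planted unfairness and deserve the
explanation. If the group-2 hazard elevation is strongly mirrored in
observed covariates, the model tracks it, and the true between-group
separation hands the cross-group pairs easy concordance — the group's
cross-group C *rises* and no disparity is visible. The deficit the audit
is meant to detect appears precisely when most of a group's excess
hazard is invisible to the design matrix; the weak channel keeps a route
through which the fairness objectives can act (they never see the label
at prediction time), and the withheld frailty supplies heterogeneity no
objective can explain away. Group effects enter only through the hazard,
never as a covariate column, mirroring the exclusion of the sensitive
attribute from predictors.

Event times use the inverse-transform
$T_i = \mathrm{scale}_k(-\log U_i / e^{\eta_i})^{1/\mathrm{shape}_k}$,
and censoring draws come from a second RNG stream derived from the seed,
so changing the censoring rate never perturbs the latent event times —
which is what lets the tests assert censoring-monotonicity against fixed
latent draws. The generator returns the latent times, the true linear
predictor and the withheld covariate for oracle checks; a linear
`coxph` fit on generated data recovers the generative coefficients
within three standard errors at $n = 20{,}000$.

What the generator does **not** emulate: the real cohort's categorical
covariate marginals and their missingness patterns, informative
(covariate-dependent) censoring, and non-proportional hazards. Passing
tests on this generator therefore show that the objectives and metrics
behave as designed under proportional hazards with group-level
heterogeneity — not that any particular real-world disparity will be
removed.

## Preprocessing

CSV input is one row per subject: time, event, group, covariates.
Categorical covariates are one-hot encoded with a dedicated `"missing"`
level whenever a value is absent — missingness is modelled as its own
category, not imputed. Continuous covariates are z-scored with
*training-split* statistics, applied unchanged to validation (standard
leakage hygiene; the constants are stored in the fit and re-applied by
`predict`). Indicator columns are left unscaled. Splits are stratified
by event status so both partitions carry the cohort's event rate. Time
units are the caller's; nothing is rescaled.

## Problem sizes used by the test suite

The packaged checks run the full pipeline at the sizes a single desk
machine handles comfortably: cohorts of $n = 20{,}000$ for the
ten-seed objective comparison (12 epochs — the step schedule has reduced
the learning rate by two orders of magnitude by then, and validation
loss has plateaued in every run we inspected), $n = 10{,}000$ for
linear-predictor recovery, $n = 50{,}000$ for distributional checks of
the generator, and exhaustive-enumeration oracles at $n \le 50$. The
benchmark reports metrics on the full cohort (train and validation
pooled): group-level metric tables for registry cohorts are customarily
reported on the whole cohort, and the 2% groups' cross-group C is far
too noisy on a 20% holdout to compare objectives; each fit's held-out
validation objective remains the early-stopping monitor.

## Known limitations

* The fairness penalty equalises *mean* predicted log-hazard across
  groups. When groups genuinely differ in average hazard this is a
  deliberate trade of calibration for parity, and it can level
  performance down as well as up.
* Group-DRO with a 2% group remains noisy even with smoothed weights;
  expect seed-to-seed variation in which objective "wins" a single
  cohort.
* Efron tie handling, time-dependent covariates, competing risks and
  discrete-time survival heads are out of scope.
* The calibration smoother is a pragmatic loess; very small groups
  (under 20 subjects) report a defined-missing ICI rather than a
  meaningless smooth.
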