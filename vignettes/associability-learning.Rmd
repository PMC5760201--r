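---
title: "Associability-modulated reinforcement learning: models, estimation, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Associability-modulated reinforcement learning: models, estimation, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`assoclearn` implements a complete analysis pipeline for adaptive two-armed
bandit loss/gain learning: a task simulator, hybrid
Rescorla–Wagner/Pearce–Hall learning models, two-stage maximum-likelihood
estimation, random-effects Bayesian model selection, behavioral validation
analyses, group contrasts on fitted parameters, and export of trial-by-trial
regressors for model-based neuroimaging. This vignette describes the models
and the design choices behind the implementation.

## The task

Subjects repeatedly choose between two novel stimuli. One stimulus yields
the better monetary outcome with probability 0.75 (the other with 0.25);
"better" in a gain block is the larger gain, in a loss block the smaller
loss. Outcome magnitudes are drawn per block from the pairs
$(0.20, 0.70)$, $(0.25, 0.75)$, $(0.30, 0.80)$ dollars, signed by
condition. Loss and gain blocks strictly alternate (starting condition
randomized per session); a block ends once the running accuracy over the
last 10 choices reaches 70% (the first block runs at least 15 trials), and
the session ends, at a block boundary, once each condition has accrued at
least 25 correct and 25 incorrect choices. The stopping rule therefore
forces at least 50 trials per condition, and because every block restarts
learning with novel stimuli, subjects are held in the learning regime
throughout.

Two implementation guards are not part of the scientific design: blocks are
capped at 60 trials and sessions at 40 blocks so that degenerate choice
policies cannot stall a simulation.

## The learning models

Expected values $Q$ of the two stimuli start at 0 in every block. On each
trial the chosen option $A$ is updated from the prediction error

$$\delta_t = R'_t - Q_A(t), \qquad
  R'_t = \begin{cases} \rho\, R_t & |R_t| \text{ is the pair's large magnitude} \\
  R_t & \text{otherwise,} \end{cases}$$

where $\rho$ (reward sensitivity) multiplies the outcome further from zero.
The basic model updates $Q_A(t+1) = Q_A(t) + \alpha\,\delta_t$ with a static
learning rate $\alpha$; the unchosen option decays,
$Q_B(t+1) = \gamma\,Q_B(t)$. The hybrid (associability) model gates the
learning rate trial-by-trial with the chosen stimulus's associability
$\kappa$:

$$Q_A(t+1) = Q_A(t) + \alpha\,\kappa_A(t)\,\delta_t, \qquad
  \kappa_A(t+1) = (1-\eta)\,\kappa_A(t) + \eta\,|\delta_t|,$$

with $\kappa$ initialized at 1 per block, floored at 0.05, and updated for
the chosen stimulus only. The associability weight $\eta$ controls how
strongly recent unsigned prediction errors reallocate attention. Choices
follow a softmax with inverse temperature $\beta$ on the current $Q$s.
With $\eta = 0$ the hybrid model reduces exactly to the basic model — a
nesting the test suite asserts at machine precision.

Two readings of the sensitivity scaling are possible: $\rho$ applied only
to the large-magnitude outcome (the "value further from 0") or to both
outcomes. The former is the default; `rho_all = TRUE` selects the
unconditional form. Only the large-magnitude reading separates $\rho$ from
$\beta$, which is also why the estimation procedure treats the two in
stages (below).

Latent traces (`latent_trace()`) record $Q$, $\kappa$, $\delta$, and the
choice probability *at the outcome event of trial $t$, before that trial's
updates*; these are the values used for reaction-time analyses, switching
regressions, and regressor export.

## Parameter bounds and units

Outcomes are in dollars ($\pm 0.20 \ldots \pm 0.80$); $\beta$ and $\rho$
scale inversely with the currency unit, so estimates under a cents
convention would be 100 times smaller for $\beta$. Optimizer boxes:
$\alpha, \eta, \gamma \in [0,1]$, $\rho \in (0,3]$, $\beta \in [0,20]$.
$\gamma$ is bounded above by 1 (decay toward zero) even though a decay
written as "range 0+" could formally exceed it; values above 1 would make
the unchosen option's value grow without feedback.

## Two-stage estimation

$\beta$ and $\rho$ are weakly jointly identified (both scale the effective
choice sensitivity), and on short adaptive sessions $\alpha$ and $\beta$
trade off along a ridge. Estimation therefore proceeds in two stages per
cohort and condition:

1. every subject is fit with $\rho \equiv 1$ and $\beta$ free;
2. every subject is refit with $\beta$ fixed at the stage-1 arithmetic
   group mean and $\rho$ free.

Stage 1 uses the same model variant as stage 2. Optimization is multi-start
(default 20 starts) quasi-Newton (`nlminb`) on scaled-logit transforms of
the bounded parameters, with starts drawn uniformly on $[-2.5, 2.5]$ in
transformed space (roughly the central 85% of each box) from a seeded
stream. Plain maximum likelihood with no priors is used; parameter-recovery
tests are the guardrail. The AICc parameter count `k_free` includes only
the final-stage free parameters (4 for the hybrid model, 3 for the basic
model; $\beta$ is excluded because it is fixed at the group mean) — the
counting convention is configurable via the fit results if a different one
is preferred.

Because the likelihood is nearly flat in $\beta$ along the $\alpha\beta$
ridge, per-subject $\hat\beta$ is noisy and right-censored at the box
bound; the group mean is consequently biased upward relative to the
generating value. This costs little likelihood (the profile is flat) and
leaves model comparison intact, but it is one reason per-subject point
estimates of $\alpha$ are noisy.

## Model comparison

Per-subject evidence is approximated as $-\mathrm{AICc}/2$ and fed into
variational random-effects Bayesian model selection: responsibilities
$u_{nk} \propto \exp(L_{nk} + \psi(\alpha_k) - \psi(\sum_j \alpha_j))$ and
Dirichlet updates $\alpha_k = \alpha_0 + \sum_n u_{nk}$, iterated to a
$10^{-4}$ tolerance on $\alpha$. Exceedance probabilities use the
regularized incomplete beta function for two models and seeded Monte Carlo
($10^6$ draws) otherwise. The Bayes omnibus risk compares the fitted
model's free energy against the equal-frequency null,
$\mathrm{BOR} = 1/(1+e^{F_1 - F_0})$, and protects the exceedance
probability: $\mathrm{PEP}_k = \mathrm{EP}_k(1-\mathrm{BOR}) +
\mathrm{BOR}/K$. The variational fixed point is checked in the tests
against direct numerical integration of the exact posterior on small
problems.

## The synthetic cohort

No behavioral dataset accompanies the analysis, so the generator creates
cohorts with the statistical structure the analyses assume: 39 PTSD-like
and 29 control subjects playing the adaptive task, loss-condition choices
from the hybrid model, gain-condition choices from the basic model
($\eta = 0$, mirroring the empirical finding that associability improves
fits in loss only), reaction times positively coupled to the chosen cue's
associability, and covariates (depression and exposure scores, age,
gender).

Parameter distributions are Gaussian on the scaled-logit transform of each
box. The defaults were calibrated once against the study's reported task
statistics and then frozen:

* $\alpha$: mean 0.50; $\beta$ (loss): mean 10 — together these produce
  fast within-block learning (first-block accuracy approaching the
  termination threshold by trial 10–15), session lengths near the reported
  50–70 loss-trial range, and a clear per-subject footprint of the
  associability model (the majority of simulated subjects favor it by
  AICc, as the majority of real participants did);
* $\beta$ (gain): mean 6 — gain choices are less value-deterministic, so
  that a minority of simulated subjects fall below the 10% switch-rate
  exclusion threshold in gain, as in the study;
* $\gamma$: mean 0.90, $\rho$: mean 1;
* $\eta$ (loss): mean 0.25 in controls, 0.70 in the PTSD-like group. The
  separation is large on purpose: group contrasts operate on *estimated*
  weights, which carry substantial estimation noise at 50–80 trials per
  subject, and the planted difference reproduces the strong group effect
  reported on real data ($t \approx 4$);
* covariate distributions produce a group/covariate variance inflation
  factor near the study's reported 1.56;
* reaction times: $0.9 + 0.232\,\kappa - 0.08\,Q - 0.002\,t + N(0, 0.35)$
  seconds, truncated to $(0.1, 6)$ s, so roughly 2–3% of trials fall
  outside the 0.333–5 s analysis window; 0.232 is the reported group-mean
  associability–RT coefficient;
* 5% of subjects per group are generated as near-non-switchers
  (perseveration probability 0.97) to exercise the exclusion filter.

What the generator does *not* emulate: within-session non-stationarity of
real subjects (fatigue, lapses), any coupling between covariates and
learning parameters beyond the group label, realistic RT distributions
(right-skew), and of course neural data. Passing tests on these cohorts
show that the pipeline recovers what it assumes, not that real data meet
those assumptions.

## Validation analyses and their design choices

* **Exclusion rule.** Subjects switching options on fewer than 10% of
  trials (strictly less) in a scoped condition are excluded; the scope is
  per-analysis (loss-only analyses keep subjects excluded only for low
  gain switching).
* **Sweep.** The associability-weight/performance sweep simulates 50
  agents of two 25-trial loss blocks at each $\eta$ from 0.05 to 0.95 in
  steps of 0.05, with other parameters at the generator means. The pooled
  correlation is computed across all 950 agents (the per-$\eta$-mean
  alternative over 19 points is also returned); performance is expected to
  be essentially independent of $\eta$.
* **Calibration.** Per subject, trials are binned into five equal-width
  bins of the model-predicted probability of the correct choice
  (a plausible alternative — pooling trials across subjects before
  binning — is not the default); empty bins are dropped with a warning.
  Equal-width edges $(0, .2, .4, .6, .8, 1)$ are used.
* **Switching models.** Random-intercept logistic regressions
  (`lme4::glmer`) of trial-wise switching on the previous outcome (coded
  1 = small loss; in gain blocks the analogous "better outcome" code is
  1 = large gain), optionally interacted with the previous trial's
  prediction error and associability value. Comparison is by AIC change
  and likelihood-ratio tests rather than coefficient p-values, which are
  unreliable in mixed models. Jackknife (leave-one-subject-out) standard
  errors are available for any cohort statistic.
* **Group contrasts.** Linear regression of a fitted parameter on group
  plus covariates, reporting the group coefficient and its variance
  inflation factor.

## Numerical choices

Softmax probabilities are computed via the stable log-logistic form;
probabilities never round to 0 or 1 within the $\beta$ box. The likelihood
recursion is implemented in C++ and checked against an independent plain-R
forward recursion on randomized toy tables. Degenerate inputs (all-same
choices, zero-variance modulators, empty calibration bins, constant
severity covariates) return boundary fits, flagged unscaled columns,
warnings, or informative errors rather than crashing.

Problem sizes in the tests and the acceptance script (40–68 subjects,
10–20 optimizer starts, 100-session task analytics) were chosen so the full
suite completes in minutes on one CPU while keeping every check at the
cohort sizes the analyses target.

## Known limitations

* Per-subject $\hat\beta$ is only set-identified on adaptive sessions; the
  two-stage group mean inherits an upward bias from the box bound. Model
  comparison and $\eta$ recovery are robust to this; $\hat\alpha$ less so.
* Maximum-likelihood estimates of $\alpha$ absorb part of the
  associability dynamics through compensation with the free $\rho$ and
  $\gamma$: across subjects, $E[\hat\alpha]$ increases with the true
  $\eta$ even when the true $\alpha$ is constant. Group contrasts on
  $\hat\alpha$ therefore have an inflated false-positive rate when groups
  differ in $\eta$ — a caveat that applies equally to the corresponding
  analysis on real data. Contrasts on $\hat\eta$ are well behaved.
* The block-termination rule truncates blocks adaptively, which caps the
  group learning curve visible at late within-block trial positions
  (blocks still alive at trial 15 are the slow ones); fixed-length
  simulation mode is available where an unselected curve is needed.
* Gain sessions of strong learners can exceed the reported 50–68 trial
  range because accruing 25 incorrect choices takes longer for
  deterministic choosers; the generator's gain inverse temperature keeps
  this moderate but the tail remains.
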