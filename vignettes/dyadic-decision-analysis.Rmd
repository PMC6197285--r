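---
title: "Measuring collective perceptual decisions: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring collective perceptual decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadwcs)
```

## The task and the question

Two observers sit side by side and perform a two-interval forced-choice
(2IFC) contrast-discrimination task: on each trial two displays of six
Gabor-like patches are shown in sequence, one display contains a target patch
whose contrast is raised above baseline, and each observer privately reports
which display contained it. When their private choices agree, the trial ends.
When they disagree, the pair must negotiate a single joint decision, which
one member enters on the pair's behalf (they take turns).

The scientific question such experiments address is whether two heads are
better than one, and by how much *given* the heads involved: a pair
containing one much better observer should simply follow that observer, so
raw joint accuracy confounds individual skill with collective skill. The
package implements the standard normalisation chain that separates them.

## The psychometric model

Each observer's private behaviour is summarised by the probability of
reporting "second display" as a function of the signed contrast difference
$\Delta c$ between the second and first display at the target location,
modelled as a cumulative Gaussian

$$P(\Delta c) = H\!\left(\frac{\Delta c + b}{\sigma}\right),$$

where $H$ is the standard normal CDF, $b$ is a response bias in contrast
units and $\sigma^2$ the variance of the internal noise. The bias-free
performance measure is the curve's maximum slope,

$$S = \frac{1}{\sqrt{2\pi\sigma^2}},$$

so small noise means a steep curve and high sensitivity. `fit_psychometric()`
estimates the model by maximum-likelihood probit regression
(`glm(..., binomial("probit"))`, the R equivalent of MATLAB's `glmfit` used in
the original analyses of this paradigm), with the mapping
$\sigma = 1/|\beta_1|$, $b = \beta_0/\beta_1$,
$S_\text{signed} = \beta_1/\sqrt{2\pi}$. The sign of the fitted slope is kept:
a *negative* sensitivity (responses anti-correlated with the stimulus) is a
meaningful data-quality signal that feeds the exclusion rule.

Joint sensitivity $S_\text{dyad}$ is estimated by the identical procedure
applied to the joint-choice series.

## The Weighted Confidence Sharing benchmark

The Weighted Confidence Sharing (WCS) model assumes that on every
disagreement the members accurately estimate and communicate the reliability
of their private opinions and weight the two opinions accordingly. For two
observers with sensitivities $s_1, s_2$ it predicts

$$S_\text{WCS} = \frac{s_1 + s_2}{\sqrt{2}}.$$

Three ratio measures follow:

* **similarity** $= S_\min/S_\max$ — how evenly matched the members are;
* **collective benefit** $= S_\text{dyad}/S_\max$ — above 1, the pair beats
  its better member;
* **optimality** $= S_\text{dyad}/S_\text{WCS}$ — 1 means the pair extracts
  everything the benchmark allows.

These are algebraically linked,
$\text{benefit} = \text{optimality}\,(1 + \text{similarity})/\sqrt{2}$, an
identity the pipeline asserts on every row it emits (tolerance $10^{-9}$).
The WCS model predicts a collective benefit only when similarity exceeds
$\sqrt{2} - 1 \approx 0.414$; below that the pair would do better simply
following its stronger member.

## The simulator

`simulate_experiment()` generates complete trial logs from the same model the
fits assume. Observer $i$ draws evidence
$d_i \sim \mathcal N(\Delta c + b_i, \sigma_i^2)$, chooses interval 2 when
$d_i > 0$, and carries confidence $|d_i|/\sigma_i$. Under the
`wcs_confidence` joint rule a disagreement is resolved in favour of the more
confident member. Because choosing the larger $|d_i/\sigma_i|$ equals taking
the sign of $z_1 + z_2$, a simulated WCS dyad's joint choices follow an exact
probit model with slope $(1/\sigma_1 + 1/\sigma_2)/\sqrt 2$ — i.e. joint
sensitivity exactly $S_\text{WCS}$ — which is what makes the simulator a
self-consistency oracle for the whole measurement chain
(`simulate_wcs_null()`).

Design choices worth knowing:

* **Confidence is $|d|/\sigma$.** Only the *ordering* of confidences matters
  for the joint choice, so any monotone transform would give identical
  behaviour; the absolute evidence z-score is the canonical choice.
  Confidence communication is noiseless, matching the benchmark's assumption
  of accurate estimation and communication.
* **Baseline rules** (`coin_flip`, `always_member1`, `best_member_oracle`)
  exist purely as test baselines with known limits: a coin flip between
  equal members reproduces the members' own curve (optimality
  $\to 1/\sqrt2$), and the oracle rule drives collective benefit to 1.
* **Ties** in confidence are broken by a seeded fair coin — a measure-zero
  event that still needs a rule for the determinism contracts.
* **Reaction times** are lognormal (private: mean-log $\log 1.4$ s; joint:
  mean-log $\log 9$ s, reflecting that negotiated decisions take seconds of
  discussion). They are conveniences for exercising the RT summaries and
  never enter any sensitivity computation. The joint RT is *absent* (not
  zero) on agreement trials, because no joint decision is made there.
* **What is not modelled:** deliberation content, learning, fatigue or
  session-dependent parameter drift. Passing the self-consistency benchmarks
  therefore shows the measurement chain is unbiased for stationary
  signal-detection observers; it cannot certify the pipeline against
  non-stationary humans, whose session effects are exactly what the session
  analyses are for.

## Trial schedules

`experiment_config()` defaults to the study conditions this package
emulates: 2 sessions × 8 blocks × 16 trials (256 trials), baseline contrast
0.15, four increments {0.075, 0.15, 0.20, 0.30} each appearing exactly 64
times, six target locations. Increment counterbalancing is exact; it is done
within each session whenever the session length is divisible by the number of
increments (as it is here, giving 32 per increment per session), so
per-session fits also see balanced designs. The target interval is drawn
uniformly per trial rather than counterbalanced — randomisation across trials
is all the task requires, and forcing exact interval balance would add a
constraint the task description does not state. Turn-taking follows the
device convention: the mouse holder enters joint decisions on odd trials, the
keyboard holder on even ones, and devices swap between sessions (both
configurable).

## Exclusion and measurement scope

A dyad is excluded when either member's accuracy is **at or below** 55%
(the threshold is inclusive) or either member's fitted slope is negative.
Non-converged fits — possible in principle with near-separated data — are
flagged with their own distinct reason rather than silently dropped, and
degenerate data (all responses identical, fewer than two stimulus levels)
raise errors instead of returning unbounded estimates. The probit fit uses a
deviance tolerance of $10^{-8}$ and at most 200 iterations.

Two measurement conventions were genuinely open and are settable:

* **Joint fit scope.** The joint psychometric fit includes agreement trials,
  with the joint response there defined as the shared private choice
  (`include_agreement = TRUE`). Joint accuracy is defined over both trial
  types, and fitting the joint series "by the same procedure" should cover
  the same trials. Disagreement-only fitting is available as a switch.
* **Egocentric bias denominator.** The reported proportion conditions on the
  disagreement trials *the member actually indicated*
  (`ego_denominator = "indicated"`): among joint decisions you entered, how
  often did you impose your own choice? This is the reading under which
  "about half of the time" is the natural null for an unbiased pair. The
  alternative (all disagreement trials as denominator) is available as a
  switch.

## Group-level statistics

`t_independent()` is the pooled-variance Student t (df $= n_A + n_B - 2$)
with Cohen's $d$ from the pooled SD; `t_one_sample()` tests collective
benefit and optimality against the model null mean of 1 with
$d = (\bar x - \mu_0)/s$. Two-sided p-values throughout, no multiple-testing
correction — matching how results in this paradigm are conventionally
reported. `mixed_anova()` fits the split-plot session-within,
group-between design via `aov()` with an `Error(unit)` stratum and reports
partial $\eta^2$; with two sessions and two groups its interaction F
provably equals the squared between-group t on within-unit session
differences, which the tests assert numerically. Type of sums of squares is
moot for the balanced, complete designs the function requires (it rejects
unbalanced input).

## Synthetic study defaults

`study_config()` defaults to two groups of 20 and 17 dyads whose member
sensitivities are drawn from $\mathcal N(1.394, 0.561^2)$ and
$\mathcal N(2.128, 0.716^2)$ respectively (truncated at 0.2), with small
biases $\mathcal N(0, 0.02^2)$ — group sizes and sensitivity distributions
chosen to mirror the younger/older adolescent samples this design was built
for. All randomness descends from one root seed through per-dyad child
seeds, so adding a dyad or a group never perturbs existing dyads' data.

```{r study, eval = FALSE}
res <- run_study(study_config(seed = 1), out_dir = "study_out")
subset(res$dyad_metrics, scope == "all",
       select = c(dyad_id, group, similarity, benefit, optimality, excluded))
res$stats
```

## Validation scale and known limitations

The packaged checks run the measurement chain at the study's own scale —
256-trial dyads, with 200 replicate dyads for the benchmark means and 100
simulated observers for parameter recovery — sizes at which the full battery
completes in well under a minute on a laptop. At 256 trials the per-dyad
ratio $S_\text{dyad}/S_\text{WCS}$ carries a small positive finite-sample
bias (under 1% in our benchmarks, vanishing by ~1000 trials), which is a
property of ratio-of-MLE estimators generally and therefore also of any
empirical study using this measure at this trial count; the benchmark
tolerance of ±0.02 on the null mean is set with that in mind.

Other limitations: no lapse-rate parameter (deliberately — adding one
changes the meaning of $S$, and the two-parameter model is the field's
convention for this task); no bootstrap CIs on psychometric parameters; the
alternative dyad models from the antecedent literature (direct signal
sharing, behaviour-and-feedback coordination) are not implemented as fitted
models — only the WCS benchmark, plus the simulation baselines above.
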