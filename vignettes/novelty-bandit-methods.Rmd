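---
title: "Modelling novelty-driven choice on a three-armed bandit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling novelty-driven choice on a three-armed bandit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noveltybandit)
```

## The scientific problem

Novel stimuli attract choice before they have ever been rewarded.
Reinforcement-learning accounts capture this with an *exploration* or
*novelty bonus*: a never-seen option enters the learner's value system
with a higher initial value than a perceptually familiar one, and that
head start decays as real outcomes accumulate. Differences in this bonus
— and in how fast it decays — are a candidate computational marker for
disorders of impulse control such as ADHD, and a candidate target of
stimulant medication.

`noveltybandit` implements the full desk-side pipeline for studying this
question on a three-armed bandit task with a novelty manipulation:
task-design generation, generative simulation of learners, bounded
maximum-likelihood fitting of the learning model and its no-bonus
baseline, nested-model comparison, behavioural outcome measures, and the
construction of the value/prediction-error parametric modulators used in
model-based fMRI. Because no behavioural data from the original
experiment are public, the package ships a synthetic-cohort generator
patterned on the published group-level parameter estimates; everything
downstream is exercised on those simulations.

## The task environment

A session is three runs of 80 consecutive trials. On every trial the
participant chooses among three images; the chosen image pays 1 unit
(£1) with a fixed per-image probability. Probabilities are drawn from a
small set (default {0.20, 0.33, 0.46}) whose mean is 0.33, assigned in
balanced rotation within each novelty class so that both classes carry
the same mean payoff. Before the task, half of the 64-image pool is
pre-familiarized; the other half is seen for the first time in-task.

On 25% of trials one of the three displayed options is replaced by an
image never shown before. We enforce the 25% as an exact count — 60 of
240 trials, 20 per run — rather than a per-trial Bernoulli draw, so the
design statistic is deterministic and testable. Replacement trials are
drawn with a minimum spacing of two trials so that two introductions
never land in the same learning window, introductions alternate between
the pre-familiarized and novel pools (30 each), the replaced option is
picked uniformly among the three on screen, and a replaced image is
retired for the rest of the session. The first trial's three images (one
familiar, one novel, one at random) are a bootstrap, not replacement
events. Screen positions are reshuffled every trial but carry no value;
all computation operates on image identity. Images and their payoff
probabilities persist across the three runs: a session is one continuous
240-trial environment.

Where the environment was under-specified we fixed one convention and
kept it: retired images never reappear (reappearance would change
first-presentation metrics), replacement events are balanced across
runs, and the reward-probability set is a configuration knob with the
{0.20, 0.33, 0.46} default.

```{r design}
design <- generate_session(task_config(), seed = 1)
design
```

## The learning model

Each image `i` holds a value `Q_i`. At its first appearance `Q_i` is
`Qf` if the image was pre-familiarized and `Qn` if not; `Qn - Qf` is the
novelty bonus. After choosing option `c` on trial `t` and receiving
reward `r(t)` (0 or 1):

```
delta(t)   = r(t) - Q_c(t)          (prediction error)
Q_c(t+1)   = Q_c(t) + alpha * delta(t)
```

Only the chosen option updates. Choice follows a softmax over the three
displayed values with inverse temperature `beta`:

```
P(c, t) = exp(beta * Q_c(t)) / sum_k exp(beta * Q_k(t))
```

The full model has four free parameters (`alpha`, `beta`, `Qf`, `Qn`);
the constrained baseline forces `Qn = Qf` and has three. Rewards are
coded 0/1 (£1 = 1.0), so initial values and the bonus are in £ units on
the same scale as the published parameter tables. Missed trials
contribute no likelihood term and trigger no update: no choice
probability is defined for a non-response. Values are eagerly
initialized per class; this is likelihood-equivalent to creating a value
at an image's first appearance, because an image's value is never
consulted before it is displayed.

## Fitting and model comparison

Each session is fitted independently by minimizing the negative
log-likelihood of the observed choice sequence with L-BFGS-B inside the
box `alpha, Qf, Qn` in `[0, 1]` and `beta` in `[0, 50]`, from 10
space-filling (Latin hypercube) starting points; the best start wins,
and a fit ending on a bound is flagged rather than rejected. The `beta`
cap is needed because an agent who always picks the max-value option
sends the likelihood surface flat toward infinite `beta`. The forward
pass is written in C++ so that calibration studies over thousands of
sessions stay cheap; an intentionally naive R implementation in the test
suite serves as its oracle. Convergence is controlled at 1e-6 on the
negative log-likelihood. When both models are wanted, `fit_models()`
fits the constrained model first and injects its optimum as an extra
start for the full model, which makes the nested-model inequality
`nll_constrained >= nll_full` hold to optimizer precision on every
dataset rather than merely in expectation.

The two models are compared with a likelihood-ratio test on the pooled
deviance. The df convention for a test pooled across sessions is
genuinely ambiguous — one freed parameter per session argues for
`df = n_sessions`, a single shared bonus parameter for `df = 1` — so the
package implements three modes: `per_session` (one pair, df = 1),
`pooled` (df = number of pairs), and `paper` (pooled deviance, df = 1,
matching the published 1-df convention). The mode is recorded in the
result object. Tiny negative deviances from finite-precision
optimization are clamped to zero.

```{r fit}
truth <- model_params(alpha = 0.45, beta = 8,
                      q_init_familiar = 0.45, q_init_novel = 0.55)
log <- simulate_agent(design, truth, seed = 2)
fits <- fit_models(design, log, fit_options(n_starts = 10, rng_seed = 1))
fits$full
likelihood_ratio_test(fits$full, fits$constrained, "per_session")
```

## Behavioural outcome measures

`summarize_behavior()` computes, per session: total amount won; the
fitted novelty bonus; the percentage of novel and of familiar
introductions chosen on the trial they first appeared ("first
presentation" of a familiar image means its first in-task appearance —
its pre-task exposure is what makes it familiar); and persistence runs —
the number of consecutive trials, starting at the introduction, on which
the introduced image was chosen — split by whether the image was
objectively optimal (strictly the highest payoff probability of the
three displayed; ties count as non-optimal) on its introduction trial.
Only replacement-event introductions enter these metrics: the three
simultaneous trial-1 images would bias any per-image rate, since at most
one of them can be chosen. Missed introduction trials leave the
denominator of the first-presentation rates, and a missed trial breaks a
persistence run (no choice was made); the missed-trial count is reported
alongside.

## The synthetic cohort

`generate_cohort()` emulates the study's design: two groups of 30
subjects (ADHD, control), each tested once on placebo and once on drug,
each session on an independently generated design (mirroring the
counterbalanced image sets). Per-cell parameter means default to the
published fitted estimates, with SDs reconstructed from the reported
standard errors as `SE * sqrt(30)`. Parameters are drawn as truncated
normals within the model bounds and independently across parameters and
sessions, with one deliberate exception: the generator draws `Qf` and
the *bonus* and sets `Qn = Qf + bonus`. Drawing `Qn` and `Qf`
independently at their reconstructed SDs (~0.35 each) would imply a
bonus SD near 0.5, five times the dispersion the published group
statistics imply (bonus SE ~0.018, i.e. SD ~0.10); the two initial
values are evidently strongly coupled within subject, and the
(Qf, bonus) parameterization reproduces the printed dispersion of the
quantity the study is about. Bonus SDs for the drug cells, which have no
published SE, reuse the placebo values.

What the generator does *not* emulate: session order and practice
effects, medication pharmacokinetics, missed-trial patterns (miss rate
defaults to 0 and is a knob), between-parameter correlations beyond the
Qf-Qn coupling, and any response-time structure. Passing tests on these
cohorts therefore validate the estimation machinery and the qualitative
group-level directions, not the real data's effect sizes: headline human
numbers (amounts won, 16.8% vs 12.3% first-pick rates) depend on
behaviour the model family does not fully capture and are not
reproduction targets. One visible instance: simulated agents pick novel
options on first presentation far more often than the human percentages,
because the fitted initial values sit at or above the incumbents'
learned values; the *direction* of every group contrast is nevertheless
preserved.

## fMRI regressor export

For each session, the constrained model's value and prediction-error
series (`Q_base`, `delta_base`) and the full-minus-constrained
differences (`Q_add`, `delta_add`) are exported as parametric modulators
of cue and outcome events: cue rows carry the chosen option's `Q_base`
and `Q_add` (chosen-option by default; all three displayed values are
available from the trace), outcome rows `delta_base` and `delta_add`.
Timing follows the task: 3.5 s stimulus, outcome 3 s after the key
press, 1.5 s outcome display, 1.5-3 s jittered intertrial interval,
4.5 s no-response display on missed trials (which produce a cue row
flagged `response = 0` and no outcome row). When no measured onsets
exist, onsets are synthesized per run with seeded jitter and response
times drawn uniform on (0.3 s, 3.5 s) — there being no published RT
distribution, and RTs affecting only outcome onsets. Modulators are
exported uncentered (mean-centering is a GLM-side choice), in a
BIDS-style events TSV. `collinearity_check()` reports the percent shared
variance between the per-trial value and prediction-error series — the
task design cannot fully decorrelate the two, and this diagnostic
quantifies the overlap on any given session.

## Numerical choices and problem sizes

* Softmax is computed with max-subtraction; `beta` is bounded at 50.
* Optimizer: L-BFGS-B, factr capped at 1e7, 10 Latin-hypercube starts;
  identical seeds give bit-identical fits.
* The LRT statistic is clamped at 0; ties in optimality labels break to
  non-optimal.
* All randomness flows through explicit integer seeds (design
  generation, agent simulation, start points, cohort sampling).

The validation suite runs at deliberately desk-friendly sizes: the
nested-model sweep refits the full 120-session default cohort; LRT
calibration simulates 1000 zero-bonus sessions of 240 trials (rejection
rate 5% with a binomial ±2-point band); parameter recovery uses 100
agents with `alpha ~ U(0.2, 0.7)`, `beta ~ U(2, 15)`,
`Qf ~ U(0.3, 0.6)`, bonus `~ U(-0.1, 0.2)`; the pooled-comparison check
uses 20 agents with a true bonus of 0.1; and the group-direction check
averages five 30-per-group cohorts. The analysis drivers under
`analysis/` default to 12 subjects per group purely to keep a narrative
run in the minutes range; the package functions scale to the full design
unchanged.

## Known limitations

* The model family is exactly the four-parameter delta-rule/softmax and
  its nested baseline; no dual learning rates, forgetting, or
  eligibility traces.
* Group-level inferential statistics (mixed ANOVAs, post hoc tests,
  correlational analyses) are out of scope: the package emits tidy
  per-session tables for any stats environment.
* The chi-square reference for the pooled LRT treats per-session fits as
  independent; subjects contribute two sessions, so `pooled` mode df is
  an upper bound on the effective degrees of freedom.
* Regressor export stops at the event table: no HRF convolution,
  design-matrix assembly, or voxelwise statistics.
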