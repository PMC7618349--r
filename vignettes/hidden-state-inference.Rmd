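---
title: "Modelling hidden-state inference in probabilistic reversal learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hidden-state inference in probabilistic reversal learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(banditSI)
```

## The task and the two candidate strategies

`banditSI` analyses behavior in a two-armed bandit with serial reversals:
one lever is rewarded with probability 0.7, the other with 0.1, and the
contingency reverses — unsignalled — after a criterion number of
high-probability-lever presses drawn uniformly from 10 to 32. A subject can
solve this in two qualitatively different ways:

* **Q-learning**: maintain a value per action, `Q(a)`, and update the chosen
  action by a learning-rate-scaled reward prediction error,
  `Q(a) <- Q(a) + alpha * (r - Q(a))`, with softmax choice
  `p(a) ∝ exp(beta * Q(a))`.
* **Hidden-state inference (SI)**: maintain a belief `b(s)` over the two
  latent lever contingencies and update it by Bayes' rule. Each action-
  outcome pair is an observation whose likelihood under state `s` is
  `0.5 + 0.5 * (+/- c)` — `+c` when a rewarded press is on the lever that is
  high under `s` (or an unrewarded press on the low lever), `-c` otherwise;
  a separate compatibility `d` may replace `c` on omission trials. The
  posterior is then mixed through a sticky transition matrix with stay
  probability `0.5 + 0.5 * gamma`, and choices follow a softmax over
  beliefs with steepness fixed at 10 (steepness trades off exactly against
  the scale of the belief, so it is not a free parameter).

Between these poles the package implements the standard intermediate agents
(random-biased choice, noisy win-stay/lose-shift, choice kernel) and the
standard Q augmentations: lateral bias, choice kernel (perseveration),
asymmetric learning rates for rewarded vs unrewarded outcomes (R/P),
counterfactual updating of the unchosen action toward `1 - r`, forgetting
of the unchosen value toward the across-action mean (reset or gradual), and
a Pearce-Hall associability that scales the learning rate by the magnitude
of recent prediction errors. `model_spec()` enumerates the families;
`param_info()` reports each model's free parameters and bounds.

## Conventions the equations leave open

Several details are not fixed by the update equations themselves; the
package resolves them as follows.

* **Initial conditions.** `Q0 = (0.5, 0.5)` (the midpoint of the binary
  reward scale), choice kernels at 0, belief uniform, and the initial
  Pearce-Hall associability `alpha0` a free parameter. Symmetric starts
  keep the first-trial choice probabilities at 0.5 for every family.
* **The SI belief update** is implemented as the standard HMM forward
  filter: multiply the prior belief by the observation likelihood,
  normalize, then apply the full 2x2 transition mix. A single-path
  transition would not use the transition matrix coherently.
* **Where the SI bias enters.** The Q-model bias sits inside the inverse
  temperature (`beta * (Q + bias)`), so the SI bias is placed inside the
  fixed steepness as well: `10 * (b(s) + bias)`. Placed outside, a bias of
  order 1 competes with a drive of order 10 and is nearly unidentifiable —
  in recovery simulations its median absolute error was ~0.2 outside the
  steepness versus ~0.02 inside, with everything else unchanged.
* **Boundary trial at a reversal.** The press that completes the criterion
  count flips the contingency immediately; its reward is drawn under the
  old contingency (the press preceded the flip), but the trial is labelled
  into the new block and is therefore "incorrect" by definition. Reversal
  curves consequently show exactly 0 at offset 0.
* **Gradual forgetting** moves the unchosen value one multiplicative step
  of size `delta` toward the across-action mean and clamps at the mean —
  the piecewise conditions in the source formulation otherwise allow an
  overshoot in one branch.
* **WSLS on trial 1** has no history and chooses uniformly. The Pearce-Hall
  associability uses the previous trial's chosen-action prediction error;
  on trial 1 that term does not exist and `alpha0` is used directly.

## Fitting, model comparison, and what is identifiable

`fit_session()` minimizes the negative log-likelihood of the observed
choices with bounded L-BFGS-B from 50 uniform-random restarts inside the
bounds (probability-scale parameters in [0, 1], inverse temperatures in
[0, 20], lateral bias in [-1, 1]); probabilities are floored at 1e-12
before the log. `compare_models()` computes per-session BIC
(`2 * nll + k * log(N)`) and the difference from the session's most
parsimonious model, breaking ties toward fewer parameters and then
declaration order. The likelihood loop is implemented once in C++ for
speed; the pure-R agent (`run_conditioned()`) is the reference
implementation, and a property test holds the two to within 1e-10 across
every family.

One identifiability caveat is worth knowing about. Under the exemplar SI
conditions (`c = 0.8`, `gamma = 0.9`, 300 trials) the profile likelihood in
`c` is nearly flat above ~0.65: the steepness-10 softmax saturates choice
probabilities once the belief passes ~0.6, so the data stop constraining
the magnitude of the compatibility and the estimate often rests at the
upper bound. `gamma` and the bias recover precisely (median absolute error
~0.01 and ~0.02); pooled across a model's unit-scale parameters the median
absolute recovery error at 20 sessions x 300 trials stays below 0.1, and
the acceptance script reports the per-parameter medians so the flatness in
`c` is visible rather than averaged away.

The exemplar pair used throughout the downstream analyses —
`exemplar_specs()` — matches augmentations across families: Q with
asymmetric learning rates and bias (`alpha_r`, `alpha_ur`, `beta`, `bias`)
and SI with `d` fixed at 0 (only rewarded trials inform the observation
likelihood) plus bias (`c`, `gamma`, `bias`).

## The synthetic-data generators

Because the package is exercised end to end on simulated data, the
generators are first-class code with fixed default conditions:

* **Behavior**: agents play `task_config()` defaults — 0.7/0.1 reward
  probabilities, reversal thresholds uniform on [10, 32], 300-trial
  sessions; the simulation unit for downstream analyses is 3 runs of 300
  trials per parameter set. Exemplar generating values are
  `c = 0.8, gamma = 0.9, bias = 0` (SI) and
  `alpha_r = 0.6, alpha_ur = 0.3, beta = 5, bias = 0` (Q).
* **Photometry** (`synth_photometry()`): the ground-truth dopamine trace is
  the per-trial RPE convolved with an exponential rise/decay sensor kernel
  (50 ms rise, 500 ms decay) at the outcome cue, sampled at 500 Hz. On top
  of it sit a slow photobleaching-like drift (amplitude 0.5, removable by a
  4th-order polynomial), a smoothed motion artifact (SD 0.3) shared with
  the 405-nm control channel, and white noise (SD 0.1). Event times follow
  the task's trial timing (0.1-1 s press delay, 0.5 s cue, 3 s ITI). These
  levels leave the preprocessed trace correlated ~0.95 with the ground
  truth — noisy enough to exercise every preprocessing stage, clean enough
  that failures indicate bugs rather than bad luck.
* **Neural populations** (`synth_population()`): each neuron draws a tuning
  class — choice, expected outcome, context (responding equally to both
  trial types of one latent context, i.e. abstract by construction),
  single-conjunction, time, or untuned — with default shares 40/20/30/0/5/5
  mirroring the recorded class proportions, a preferred condition, and a
  Gaussian within-trial temporal field; activity is baseline + gain x
  tuning + truncated Gaussian noise, mimicking deconvolved spike
  probabilities.

What the generators deliberately do **not** emulate: session-to-session
nonstationarity, within-trial reaction-time structure, correlated noise
across neurons (except via `pseudo_population()`'s explicit destruction of
it), hemodynamic-like artifacts beyond a linear shared component, and any
mismatch between the agent family generating behavior and the family being
fit. Passing tests therefore demonstrate internal consistency of the
analysis chain, not that real mice use these exact strategies.

## The dopamine regression and its predictors

`ridge_cpd()` regresses the time-warped dopamine response across trials on
six predictors — outcome, previous outcome, choice, previous choice (all
coded +/-0.5) and the continuous Q-RPE and SI-RPE — with 2-fold
cross-validated ridge regression (folds split by alternating blocks to
avoid leakage; penalty chosen per timepoint from a log-spaced grid by the
full model's held-out error). The coefficient of partial determination for
predictor `j` is `100 * (SSE_without_j - SSE_full) / SSE_without_j` on
held-out folds. Only trials within 6 trials of a contingency switch enter:
those trials contain the incongruent histories that dissociate the two RPE
definitions.

The RPE predictors are computed by conditioning the two exemplar agents at
fixed reference parameters on each session — the same use of average
fitted parameters for trial-by-trial model predictions as in the
behavioral analyses. The alternative of refitting both exemplars to each
simulated session is supported (`refit = TRUE` in `rpe_signature_run()`)
but has a known failure mode on synthetic data: agent-generated choices
are nearly deterministic, and a refitted Q model can then mimic the SI
belief dynamics almost exactly (RPE correlation ~0.998), leaving the
variance split between the two predictors undetermined. With fixed
reference parameters the generator's RPE wins the CPD contrast in
essentially every run, and the contrast flips with the generator.

SI-RPE uses the task's true reward-probability matrix by default
(`[[0.7, 0.1], [0.1, 0.7]]` by choice x state); the matrix is an argument
because a fitted matrix is equally defensible.

## Decoding choices and latent context

Decoding uses window-averaged activity (1 s before initiation up to the
outcome cue, i.e. the full within-trial grid of the synthetic data), a
linear SVM with its regularization grid-searched by 5-fold CV on the
training side, 250 balanced pseudo-trials per class, and at least 100
random 75/25 splits. Unique trials are split into train and test *before*
resampling: resampling first and splitting the pseudo-trials would place
copies of the same trial on both sides and push even the label-shuffled
control far above chance. Cross-condition generalization (`ccgp()`) trains
on one condition pair of a dichotomy and tests on the held-out pair (for
context: train RH vs LH, test LL vs RL, and the symmetric split); abstract
context cells give CCGP near 1 while pure conjunction cells give CCGP
scattered around 0.5 — individual populations can deviate substantially
because train-silent neurons acquire small noise-driven weights, so CCGP
statements are made about averages over populations.

Permutation p-values for the selectivity index
(`SI = (f+ - f-) / (f+ + f-)`) use add-one smoothing,
`p = (1 + #{|SI_shuffle| >= |SI_obs|}) / (1 + n_shuffles)`, which keeps
them in (0, 1] and calibrated under the null (checked by KS test on
untuned populations).

## Numerical choices and degenerate inputs

* Probability floor 1e-12 in the likelihood; belief normalization after
  every filter step.
* Optimizer starts are drawn strictly inside the bounds (offset 1e-6 x
  range) so finite-difference gradients at the boundary stay defined;
  non-finite objective values are replaced by a large constant.
* The reversal-latency fit `p(t) = p_inf - (p_inf - p0) * exp(-t / tau)`
  falls back to a level-based answer (0 if the curve lies above 0.5, `Inf`
  if below) when the least-squares fit degenerates on flat curves; the
  50% crossing is `-tau * log((p_inf - 0.5) / (p_inf - p0))`.
* The elastic-net grid search maps the inverse regularization strength `C`
  to the glmnet penalty `lambda = 1 / (n * C)` and scores by held-out
  deviance R-squared; a session whose subject never switched levers is a
  single-class target and errors out.
* Strategy-consistency ties (model probability exactly 0.5) are excluded
  from that model's denominator and counted separately.
* Problem sizes used by the test suite and the acceptance script — 20
  sessions x 300 trials for recovery, 3 pooled sessions x 10 seeded runs
  per generator for the dopamine contrast, 60-neuron populations with 3
  replicates for the decoding contrasts, 200 neurons for null calibration —
  are the package's chosen simulation scale: large enough for the reported
  contrasts to be stable, small enough to run routinely.

## Known limitations

* `c` near its upper bound is reported as fitted; no profile-likelihood
  interval accompanies it.
* The two-action, binary-reward setting is hard-coded; no continuous
  rewards, no more than two levers.
* Fold assignment in `ridge_cpd()` is by block parity; with a single
  completed block it falls back to an interleaved split.
* The switch-probability history labels read backwards from the reference
  lever at `t-1`, so the first position is always "S"; histories are
  comparable across sessions but not with codings that reference the
  current trial.
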