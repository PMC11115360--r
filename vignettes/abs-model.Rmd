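---
title: "The autocorrelated posterior-sampling model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The autocorrelated posterior-sampling model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(absampler)
```

## The model

`absampler` simulates a process model of judgment and decision-making in
which all behavior is generated from *samples of hypotheses* drawn from a
posterior distribution, rather than from the posterior itself.  A trial is
described by a posterior over fine-grained hypotheses (for the running
numerosity example, the exact number of dots shown on screen), built by
Bayes' rule from a prior and a likelihood.  The mind is assumed to have
only local access to this posterior: it generates a serially dependent
stream of hypothesis samples with a Metropolis-coupled MCMC sampler (MC3,
parallel tempering), whose cold chain reports the samples.

Every behavioral measure is a simple transform of the sample stream:

* **Choices.**  The hypothesis axis is partitioned into response
  alternatives; each sample supports the alternative whose interval contains
  it.  Evidence tallies, seeded by the pseudocounts of a Beta/Dirichlet
  *response prior*, accumulate until the max-minus-next stopping rule fires:
  sampling stops once the leading alternative's total exceeds the runner-up
  by a threshold `delta`.
* **Probability and confidence judgments.**  The reported probability that
  alternative *m* is correct is the posterior mean
  `(alpha_m + S_m) / (N + sum(alpha))`, which tempers small samples toward
  the prior mean.  Decision confidence is the same quantity for the chosen
  alternative; at a max-minus-next stop with binary prior Beta(i, j) it
  equals `(i + j + N + delta) / (2 (i + j + N))`, so decisions that needed
  more samples are less confident.
* **Estimates.**  The most recent sample (the default), or the sample mean.
* **Confidence intervals.**  Produced from symmetric fractional order
  statistics of the samples with linear interpolation (the 60% interval
  from five samples is the 2nd and 4th order statistic); evaluated as the
  proportion of samples falling inside a given interval.
* **Response times.**  Samples arrive as a Poisson process at rate `lambda`,
  so a trial of `N` samples takes an Erlang(`N`, `lambda`) time plus a
  nondecision constant `t0`.

The response prior adapts to feedback: after each trial it is reset to a
uniform Beta/Dirichlet with one extra pseudocount on the alternative the
previous trial's feedback marked correct (binary: Beta(2,1) or Beta(1,2)).
Only the immediately preceding trial is used.

Three ablations isolate the active ingredients: `no_prior` (all
pseudocounts zero, no adaptation), `direct_sampling` (i.i.d. samples), and
`fixed_sample_size` (always N = 5 samples, no optional stopping).

## Sampler configuration

The local sampler is the one free component whose details the behavioral
predictions depend on, and the one least constrained by theory.  The
package default is

* 4 chains at temperatures `1, 8, 64, 512` (tempering a Gaussian by `T`
  widens it by `sqrt(T)`, so the hot chains relax over progressively longer
  timescales),
* Gaussian proposals with standard deviation `0.25` times the posterior sd
  (one-cell steps on discrete grids),
* one adjacent-pair swap proposal per iteration (`swap_prob = 1`).

This operating point was chosen because it jointly realizes the model's
documented regimes, which pull in different directions:

* Long-range (1/f) dependence of repeated estimates requires slow mixing
  and a ladder of relaxation timescales.  The small proposal makes the cold
  chain locally persistent; the geometric temperature ladder adds slower
  components; frequent swaps carry them into the cold chain.  A plain
  random-walk chain with this proposal is close to a random walk over a
  1024-trial window (slope near the steep edge of the 1/f band), while
  configurations with near-unit proposals and narrow ladders whiten the
  estimate series almost completely — both miss the 1/f band that the full
  model is supposed to occupy.
* Slow errors in difficult, accuracy-emphasised choices require enough
  within-trial persistence that evidence arrives in runs, producing
  drawn-out tug-of-war error paths.
* Fast errors in easy, speeded choices require the opposite: the error RT
  advantage created by a misaligned adaptive prior is diluted by every
  multi-sample error excursion.  Frequent swaps act asymmetrically here:
  a cold chain stuck on the wrong side of an easy boundary sits in a
  low-probability tail and is almost always rescued by a swap, while a
  chain dithering at a difficult boundary is not.  This difficulty-dependent
  rescue is what lets one configuration produce both error-speed regimes.

Sampler initialization is task-dependent.  Batteries of unrelated decision
problems re-initialize the chains from each trial's posterior (otherwise
the previous trial's stimulus side leaks into the next trial's starting
point, which reverses the slow-error pattern and hands the no-prior variant
a spurious fast-error effect).  Repeated-estimation batteries keep the
chain state across trials — this cross-trial carryover is precisely the
mechanism behind the 1/f structure in estimate series.  An anchored trial
overrides both: every chain starts at the comparison value h*.

## Task batteries and default parameters

Difficulty is operationalized as the offset of the posterior mean from the
decision boundary in posterior-sd units (`d_hard = 0.5`, `d_moderate = 1`,
`d_easy = 2`); emphasis as the stopping threshold (`delta_speed = 2`,
`delta_acc = 5`).  The posterior sd is 3 hypothesis units (dots), the
boundary 25, the sampling rate 10 samples/s, and `t0 = 0.2` s.  Judgment
queries use a fixed budget of `n_judgment = 5` samples; conjunction queries
get half that budget (rounded up), reflecting the greater cost of tallying
a conjunctive event.  Effects use `n_trials = 10^4` trials per condition;
the fast-error battery uses ten times as many because its effect is a
fraction of one sampling interval and the battery's Monte-Carlo standard
error must be held well below it.  Spectral batteries use 10 simulated
participants with 1024 trials each.  The decision-then-estimation battery
draws stimulus means uniformly from [21, 30] with a near anchor at 25.5 or
a far anchor at 75.5, and uses its own threshold `delta_anchor = 16`: the
anchored decision must outlast the sampler's escape from h* for the
stopping rule's selection to act; with speeded thresholds every
local-sampling variant is purely attracted to the anchor.

Standard errors for all battery statistics come from contiguous trial
blocks (20 by default), so serial dependence inflates them honestly.  Each
directional criterion is a one-sided test at three standard errors.

## The reference ablation grid

`table2_expected()` records which effects each variant should reproduce.
Most cells follow directly from the ingredient structure: prior-driven
probability biases (conservatism, explicit subadditivity, conjunction
fallacy, partition dependence) fail only for `no_prior`; autocorrelation
effects (anchoring, 1/f) fail only for `direct_sampling`;
optional-stopping effects (Q-Q fanning, within-condition confidence-RT
coupling, repulsion) fail only for `fixed_sample_size`; slow errors need
autocorrelation *and* optional stopping; fast errors need the adaptive
prior *and* optional stopping.

Two cells deserve comment because the package's analysis forces them:

* *Resolution of confidence, fixed sample size.*  Confidence at fixed N is
  a monotone transform of the evidence tally.  Whenever that tally is
  informative enough about accuracy to produce a positive meta-d' (which
  all variants, including this one, are supposed to do), its mean is
  necessarily higher on correct trials — so the variant shows resolution.
  Suppressing resolution at fixed N would require strictly unanimous
  evidence on every trial, which would simultaneously abolish the
  metacognition effect.  The grid therefore marks this cell as passing.
* *Cross-condition confidence-RT relation, no prior.*  With all-zero
  pseudocounts the stopped confidence is `(N + delta) / (2N)`, which equals
  1 on unanimous trials regardless of the threshold.  Under run-like
  autocorrelated evidence, unanimous short trials dominate the speeded
  condition, so raising the threshold cannot raise mean confidence.  The
  positive cross-condition relation is carried by the response prior's
  tempering of small samples, and the grid marks the no-prior cell as
  failing.

## Numerical choices and degenerate cases

* Boundary membership is half-open: a hypothesis exactly on a cut point
  supports the upper alternative (deterministic, measure-zero for
  continuous posteriors).
* Rejected Metropolis proposals repeat the current position, and the
  repeated value is a reported sample; there is no burn-in anywhere —
  starting-point effects are mechanism, not nuisance.
* "Exceeds the threshold" is implemented as `>=` on integer evidence, so a
  sufficiently biased prior can stop with zero samples (rt = t0, confidence
  from pseudocounts alone).  A cap of 1000 samples per trial forces a
  majority decision if the threshold is unreachable; argmax ties break
  uniformly at random.
* Interval production clamps interpolated bounds to the sample range;
  interval evaluation uses the closed interval and defaults to the raw
  (untempered) proportion.
* Hit and false-alarm rates are clamped into `[1/(2n), 1 - 1/(2n)]` before
  the normal quantile; meta-d' criteria are evaluated on the achievable
  confidence grid of the simulation, not a continuous sweep.
* Spectral slopes come from an ordinary least-squares fit of log10 power on
  log10 frequency over all Fourier frequencies except DC, on the raw
  mean-detrended periodogram.  The 1/f band is a slope in [-1.5, -0.5];
  |slope| < 0.25 counts as white and slope <= -1.75 as a random walk; the
  latter two cutoffs are package choices.
* All randomness flows through R's global RNG, which the C++ sampling
  kernels also consume, so a single `set.seed()` makes entire experiment
  runs bit-reproducible.

## What the generator does and does not emulate

The synthetic tasks capture the structure of the laboratory paradigms —
difficulty-controlled Gaussian posteriors, random correct sides, trial
feedback, anchored comparisons, repeated estimation of a fixed quantity —
but not perceptual encoding, motor output beyond the scalar `t0`, lapses,
or any parameter heterogeneity across simulated participants.  Passing the
battery shows that the mechanism produces the qualitative phenomena under
these idealized conditions; it says nothing about quantitative fits to any
human dataset, and no human data are used anywhere in the package.

## Known limitations

* The dynamic-programming optimal stopping policy is a documented stub;
  only the max-minus-next heuristic and fixed-N rules are implemented.
* Hypothesis spaces are one-dimensional (continuous Gaussian or a discrete
  grid); hierarchical or multivariate representations are out of scope.
* The sampler's defaults are an operating point, not an estimate: nothing
  here fits the model to data, and other configurations trade the regimes
  off differently (the vignette section above documents the direction of
  each trade-off).
* Chain updates are sequential by contract; there is no parallel execution.
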