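---
title: "Models, opponent algorithm, and pupil regression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, opponent algorithm, and pupil regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matchpennies)
```

This vignette documents the scientific model behind `matchpennies`, the
parameters that matter, the choices we made where the design was genuinely
open, and what the synthetic-data tests do and do not establish.

## The task and the opponent

In iterative matching pennies the mouse and a computer each choose left or
right every trial; the mouse is rewarded iff the choices match. The
computer exerts competitive pressure by prediction: it keeps the mouse's
entire within-session choice and outcome history and, before each trial,
estimates nine conditional probabilities that the mouse will choose left —
given the preceding *N* choices (*N* = 0..4) and the preceding *N*
choice–outcome combinations (*N* = 1..4). Each estimate is tested against
0.5 with a two-sided exact binomial test. If nothing is significant the
computer plays a fair coin; otherwise it takes the significant estimate q\*
farthest from 0.5 and counters it.

Open choices we had to fix:

* **Significance level.** Not specified by the task description; we default
  to `alpha_test = 0.05` (configurable), the conventional level in the
  primate implementations this opponent descends from.
* **Stochastic vs deterministic counter.** "Generate the counter choice
  with the significant conditional probability" admits two readings. Our
  default is the stochastic one — the computer plays left with probability
  1 − q\* — which matches the standard "algorithm 2" reading and avoids a
  trivially exploitable deterministic opponent. `counter_mode =
  "deterministic"` is available.
* **Ties** between equally deviant significant estimates resolve by fixed
  table order (choice conditions N = 0..4, then choice–outcome N = 1..4).
* **Unseen suffixes** (zero matching occurrences) report estimate 0.5 with
  p = 1 and are never treated as significant.
* **MISS trials** are excluded from the opponent's histories (unstated in
  the task description); simulated agents never miss, so the
  session-termination-by-miss rule is not exercised by the simulator.

With `alpha_test = 0` the opponent never rejects and is exactly a fair
coin, which gives every agent a 50% expected reward rate — the property the
acceptance suite checks at the Nash point.

## Trial timing

Each trial: a 2-s response window, a fixed 3-s consumption period, then an
intertrial interval drawn from Exp(1/3) truncated to [1, 5] s. Licks during
the ITI append further draws, up to five in total. We sample by inverse CDF
on the renormalized interval rather than rejection, so traces are
bit-reproducible under a seed. Consequently the post-outcome delay on
lick-free trials spans exactly [4, 8] s.

## The decision models

Five models, all with choices in {L, R} and outcomes r in {0, 1}:

* **WSLS** — follow win-stay–lose-switch with probability `p_wsls`; 0.5 on
  the first trial.
* **Q_RPE** — chosen value moves toward the outcome at rate `alpha`;
  unchosen value unchanged; softmax with inverse temperature `beta`.
* **FQ_RPE** — as Q_RPE, but the unchosen value decays by `(1 - alpha)`
  ("forgetting").
* **DQ_RPE** — chosen value moves toward 1 at `alpha_r` after reward and at
  `alpha_u` after non-reward. The toward-1 unrewarded update is implemented
  exactly as defined; a `dq_unrewarded_toward_zero` flag provides the more
  conventional variant for comparison.
* **FQ_RPE_CK** — the hybrid: FQ_RPE values plus choice kernels that move
  toward 1 (chosen) / 0 (unchosen) at rate `alpha_k`, combined as
  `beta * Q + beta_k * K` in the softmax. The kernels capture perseveration
  that is independent of reward.

Parameter box: learning rates and `p_wsls` in [0, 1]; `beta`, `beta_k`
positive. Initialization of values and kernels is not specified by the
source analyses; we use Q0 = K0 = 0 (configurable), which keeps the
first-trial choice probability at 0.5 and, with outcomes in {0, 1},
guarantees by induction that all values and kernels stay inside [0, 1].
Softmax probabilities are computed with max-subtraction and floored at
1e-12 before logs.

Per-trial latent variables exposed for the pupil regressions: pre-choice
Q and K for both sides, their differences dQ and dK, the chosen value and
kernel, the model probability of choosing left, the reward prediction
error RPE = r − Q(chosen), and the choice-kernel error CKE = 1 − K(chosen).

## Fitting and model comparison

Choices and outcomes are concatenated across sessions; the agent state
resets at each session boundary (sessions are separate days — the source
description does not state this; resetting is the conservative choice and
makes the likelihood invariant to session order, which is tested).
MISS trials contribute no likelihood term and no update.

The likelihood forward pass is written in C++ for speed; an independent
plain-R forward pass (`latent_trajectory()`) is kept as the oracle and the
two are tested for equality across all five models. Optimization is
multi-start L-BFGS-B (default 10 seeded random interior starts — the
surface is nonconvex, particularly for the hybrid model at low `beta`).
Inverse temperatures are optimized on the log scale with an upper cap of
100, since the box only constrains them to be positive. BIC uses
`2 nll + k log n` with n the number of non-MISS choice observations and
k the free-parameter counts 1 (WSLS), 2 (Q_RPE, FQ_RPE), 3 (DQ_RPE),
4 (FQ_RPE_CK). Because it is not stated whether comparisons are summed or
averaged over sessions, the comparison table reports both.

Parameter recovery at the published operating point (alpha = 0.60,
alpha_k = 0.13, beta = 0.52, beta_k = 1.63; 5,000 trials per replicate) is
noisy per replicate for `alpha` — at `beta` ≈ 0.5 the likelihood is flat in
the learning rate — but unbiased: the acceptance test asserts the mean over
20 replicates within ±0.10 for the learning rates and ±25% for
`beta + beta_k`.

## Behavioral statistics

**Three-choice entropy.** Shannon entropy (base 2) of the frequencies of
the eight patterns of three consecutive choices, counted over all
overlapping windows (stride 1 — this maximizes counts and matches the
30-trial running version). The maximum is 3 bits; an i.i.d. fair coin
approaches it with the usual plug-in bias of order (K−1)/(2N ln 2).

**Session truncation.** Animals end sessions by repeating one side before
ceasing to respond. We compute the running entropy of a 30-trial window,
fit a piecewise-linear function with at most one slope change (the original
analysis used a packaged linear change detector; we emulate it with a
least-squares single-breakpoint scan selected against a single line by
BIC — documented as an approximation), and truncate at the first fitted
crossing below 1 bit. If the fit recovers above threshold later, or never
crosses, the session is kept whole.

**Preference switches** have no operational definition in the source
methods; we count crossings of 0.5 by a Gaussian-smoothed (sd = 5 trials,
configurable) running choice average.

**Psychometric curve.** Trials are pooled and binned by the softmax input
`beta*dQ + beta_k*dK`; the observed fraction of left choices per bin is
compared with the softmax of the bin center. For a simulated softmax agent
the two converge as trials grow; the suite checks a maximum deviation below
0.05 in bins with at least 100 trials.

**Kernel-weight sweeps.** Holding the learning rates and `beta + beta_k`
fixed and varying w = `beta_k / (beta + beta_k)` over [0, 1] (11 points,
20 × 500-trial sessions per point by default): against the opponent the
reward rate is flat for w ≤ 0.5 and declines markedly at the pure-kernel
end (about 6–7 percentage points at the fitted-median operating point —
a pure-kernel agent with `beta_k` ≈ 2.15 has a repeat probability capped
near 0.90, which bounds how exploitable it can become); in the bandit the
rate is maximal at w = 0 and falls monotonically, since kernels fight the
reward gradient there.

## Pupil pipeline

Preprocessing is applied in a fixed order: (1) zero-phase 4-Hz lowpass —
the filter family is not specified by the source; we use a 4th-order
Butterworth applied forward and backward so trial alignment suffers no
phase distortion, with coefficients derived in-package via the bilinear
transform (no DSP dependency) and validated against the closed-form
magnitude response; (2) frames more than 3 scaled MADs from the whole-trace
median are masked; (3) z-scoring with a 10-min centered moving window
(mean and SD; a moving-mean-only mode exists because the source is
ambiguous) to absorb slow drift. Masked frames are excluded from all
statistics and linearly interpolated only for trial binning. Degenerate
cases are guarded: constant traces z-score to 0, and traces shorter than
the window fall back to global statistics with a warning.

Trial responses subtract the mean z over [−2, −1) s before the cue and are
averaged in 80 100-ms bins spanning [−3, 5] s. Trials whose window leaves
the trace are dropped and logged.

Three regression designs (choices dummy-coded 0 = left, 1 = right):
*observable* (choices, outcomes, and interactions for the next, current,
and two previous trials, plus the 20-trial moving-average reward and the
normalized cumulative reward), *selection* (adds dQ, chosen value, dK,
chosen kernel), and *updating* (adds RPE and CKE). The moving average is
computed over the 20 most recent trials including the current one, exactly
as the defining sum is written; before trial 20 it is renormalized over the
available history rather than dropping rows (flagged in the output).
Rows missing a required lead/lag (the first two trials and, for the
observable design, the last) are dropped — zero-filling the session-edge
lead terms was the alternative and we prefer dropping, as it makes no
distributional assumption.

Per session and per bin, ordinary least squares gives coefficients and
two-sided p-values; aliased columns in rank-deficient designs are dropped
with a warning. Across sessions we report the fraction significant at
p < 0.01 per predictor per bin, a one-sample proportion chi-squared test
(no continuity correction) against the 1% chance level, and bootstrap
percentile 95% CIs on mean coefficients (1,000 resamples over sessions;
the source states a bootstrap without the scheme). No multiple-comparison
correction is applied, deliberately mirroring the source analysis. The
RPE-sign split refits the updating design separately on positive- and
negative-RPE trials (outcome is constant within each group, so
outcome-confounded columns alias out automatically); empty groups are
flagged. The two-eye analysis pools per-session, per-bin coefficients of
one predictor inside [3, 5] s and reports their Pearson correlation.

## Synthetic data: what it emulates and what it does not

`generate_behavior()` wraps the closed-loop simulator; its default agent is
the hybrid model at the fitted-median-consistent operating point
(alpha = 0.60, alpha_k = 0.13, beta = 0.52, beta_k = 1.63, i.e.
alpha_k/alpha = 0.22, beta_k/(beta+beta_k) = 0.76, beta + beta_k = 2.15),
which produces sessions with entropy above 2.5 bits and reward rates a few
points below 50% — the qualitative ranges of trained animals.

`generate_pupil()` plants, per trial, a linear combination of design-matrix
regressors with raised-cosine-flanked plateau kernels (0.5-s ramps, flat
top, so interior 100-ms bins carry exactly the planted coefficient), on top
of slow sinusoidal drift (default amplitude 0.3 z units, 20-min period),
band-limited noise (pre-shaped below the lowpass cutoff so preprocessing
leaves its variance intact), and sparse outlier spikes (rate 0.1% of
frames, 10 × trace SD) that exercise the MAD mask.

One numerical point deserves emphasis: **a moving-window z-score is
invariant to any affine rescaling of the raw trace**, so no generator can
make the pipeline recover planted coefficients on their stated scale unless
the z-space signal has unit windowed SD. The default `noise = "calibrated"`
therefore sets the noise SD to `sqrt(1 - var(planted) - var(residual
drift))`, which is the precise sense in which the generator is "the inverse
of the preprocessing conventions". With an explicit `noise_sd` the
recovered coefficients scale by 1/SD(z-space signal); for noiseless
exactness checks use `zscore = "none"`, under which OLS returns the plant
up to filter edge effects. Calibration requires the planted variance to
stay below 1 z²; the generator warns and floors the noise otherwise.

Realistic cue spacing (≈ 6 s median) makes adjacent [−3, 5] s trial windows
overlap, so a trial's early bins and baseline contain the previous trial's
response. This is faithful to real recordings and is absorbed by the lagged
regressors on average, but it adds per-session projection noise; tests that
assert exactness therefore widen the spacing, and recovery tests average
over sessions.

What a green synthetic test does **not** establish: that real pupil data
satisfy the linear model, that real mice sit at the default operating
point, or any of the published animal-data magnitudes (trial counts, the
44% reward rate, the 2.87-bit entropy, the r = 0.83 two-eye correlation) —
those depend on the animals and are used here only as qualitative ranges.

## Numerical choices and limitations

* Exact binomial p-values against 0.5 use the symmetric two-sided closed
  form (verified against `binom.test`), vectorized for the per-trial loop.
* The opponent's suffix counts are updated incrementally (O(1) per trial
  with integer-coded patterns), and tested against brute-force suffix
  scanning.
* The bandit's switch draw happens at trial start once ten hits have
  accumulated, so post-criterion block lengths are geometric with mean 11.
* `detect_last_trial` returns the whole session for degenerate inputs
  (shorter than the window) rather than erroring.
* The piecewise-linear truncation fit scans all breakpoints with a minimum
  segment of 5 windows; this is O(n²) in session length, fine at the
  ~500-trial scale.
* Sweeps and recovery harnesses are Monte-Carlo; all stochastic tests fix
  seeds and state their tolerances in terms of the induced standard errors.
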