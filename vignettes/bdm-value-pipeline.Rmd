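---
title: "Subjective value from BDM bids and dopamine-like responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subjective value from BDM bids and dopamine-like responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdmvalue)
```

This vignette explains the models and numerical procedures behind
**bdmvalue**: what each analysis assumes, which parameters matter, what the
synthetic generator does and does not emulate, and where genuinely open design
choices were resolved.

## The auction mechanism

The Becker-DeGroot-Marschak (BDM) mechanism is a second-price sealed-bid
auction against a random opponent. The bidder starts each trial with a water
budget $B$ (default 1.2 ml) and bids a fraction $b \in [0,1]$ of it for a
juice reward; the opponent's bid $c$ is uniform on the bid space. Winning
(ties included, $b \ge c$) delivers the juice plus $B - cB$ of water — the
price paid is the *opponent's* bid. Losing delivers the full budget and no
juice. Integrating over the uniform opponent gives

$$E[\text{payoff}](b) = B + \frac{v\,bB - (bB)^2/2}{B},$$

for a bidder who values the juice at $v$ ml-water-equivalent, maximized at
$bB = v$ with value $B + v^2/(2B)$: truthful bidding is optimal (incentive
compatibility). `expected_payoff()` implements the closed form,
`incentive_compatibility_check()` verifies it against a 0.001-step grid
search, and the test suite additionally checks it against numerical
quadrature and Monte-Carlo simulation. Bids are represented internally as
fractions of the budget; conversion to ml happens only at I/O, which keeps
one canonical unit throughout.

The mechanism is deliberately agnostic about the juice-to-water exchange
rate: the subjective value $v$ enters in ml-water-equivalent units supplied
by the caller, and the behavioral simulator works directly in bid-space
units. No utility curvature or probability weighting is modeled — with three
fixed reward magnitudes there is nothing to identify it from.

## The synthetic bidder

`simulate_behavior()` generates sessions whose bids carry the statistical
structure the downstream analyses assume:

* **Latent subjective value**: a per-session offset
  ($\mathcal N(0, \sigma_{session})$) plus a within-session AR(1) scalar
  (coefficient $\phi$, innovation $\sigma_{trial}$), *shared across the three
  reward magnitudes*. This is the simplest process that produces coherent
  trial-by-trial and day-to-day bid fluctuation across magnitudes; setting
  `shared_drift = FALSE` gives each magnitude its own process.
* **History effects**: weighted contributions of the starting cursor
  position, cumulative liquid consumed (satiety), the previous
  same-magnitude computer bid, the previous same-magnitude result, and
  same-magnitude win/lose streaks, each with a configurable weight in
  bid-space units.
* **Noise and clipping**: independent Gaussian bid noise, with the final bid
  clipped to $[0,1]$.
* **Failed trials**: a small configurable fraction (default 2%) of trials
  fail (no stable bid); they deliver nothing and are excluded from analyses,
  but the following trial records that its predecessor failed.

Default parameters: base values $(0.2, 0.5, 0.8)$ spreading the three
magnitudes over the bid space (emulating a reward range calibrated so the
full bid range is used), $\phi = 0.97$, $\sigma_{trial} = 0.025$ (stationary
sd $\approx 0.10$), $\sigma_{session} = 0.10$, bid noise $0.05$. Weights
default to small values with the signs one expects from satiety and
win-stay/lose-shift adjustments.

`study_scenario()` fixes four named departures from the defaults, each tied
to an analysis regime: `"decoding"` (800-trial sessions, faster-mixing
larger-amplitude drift: $\phi = 0.9$, $\sigma_{trial} = 0.09$) so that every
neuron's session represents all ten bid tenths, which the pseudo-population
balance rule requires; `"overlap"` (base values $0.4/0.5/0.6$) so that bids
for different magnitudes fall within 5% of each other and matched-bid
comparisons have matches across all pairs; `"coherent"`
(drift sd $\gg$ noise sd) as the signal-dominant coherence condition; and
`"independent"` (no drift, no shared history effects) as the coherence null —
note that even an *independent* slowly drifting value per magnitude produces
spurious rank correlations in finite sessions, so the honest null removes
drift entirely.

What the generator does **not** emulate: eye movements, licking, lever
dynamics (only scalar per-trial velocity and absement covariates, by default
independent of everything), risk attitude, satiety nonlinearity, or any
biological claim about dopamine. Passing tests therefore show that the
*procedures* behave as intended on data with the assumed structure — they
say nothing about real neurons.

## The synthetic neuron

`simulate_neuron()` implements the canonical two-component phasic response:
a value-independent "attentional" excitation (default 90–180 ms after
fractal onset, +12 Hz) followed by a "value" component (default 180–340 ms)
whose rate is `baseline + gain × (signal − mean_prediction)`. The signal is
the trial's upcoming bid (`coding_target = "bid"`), the magnitude level's
mean value (`"magnitude"`), or absent (`"none"`); `mean_prediction` is the
across-trial mean value carried by the preceding trial-start cue, so the
value component encodes a *bidirectional prediction error*: below-prediction
signals depress the rate (floored at 0 Hz). Spike counts are Poisson in 1 ms
bins from −500 to +1000 ms around fractal onset. The floor introduces a mild
convexity in the rate-versus-bid relation at low bids; it is the price of
non-negative rates and mirrors the limited dynamic range of real depressions
from a sub-10 Hz baseline.

One ambiguity was resolved as a documented default: the baseline period is
defined as the 500 ms preceding *fractal onset* (rasters are aligned to the
fractal; a trial-start-cross-aligned baseline would require a second
alignment and differs only by the fixed 500 ms cue interval).

## Behavioral value models

`build_regressors()` constructs the 31 candidate variables (reward value,
starting bid, prior liquid, day of week, session/trial indices, previous
trial fate and results, overall competing-bid lags 1, 2, 3, 5, 7,
same-magnitude competing-bid lags 1–10 and running means over the last 2–6
same-magnitude trials, win/lose streaks). Lags undefined at session starts
are missing and dropped listwise at fit time, never imputed; streaks reset
at session boundaries. Equality with a brute-force per-trial recomputation
is asserted in the tests.

`lasso_select()` uses cross-validated lasso (glmnet) with the
one-standard-error rule: $\lambda_{1SE}$ is the largest $\lambda$ whose CV
error is within one SE of the minimum, favoring sparser models. The fold
count defaults to 20 and is configurable up to whatever the data support —
extremely large fold counts approach leave-one-out and are accepted when
row counts allow. Day of week enters as one-hot dummies (any selected dummy
counts as selecting the variable); previous-trial-failure is binary.

`fit_mixed_model()` fits one of three nested mixed-effects structures
(lme4/lmerTest, Satterthwaite p-values, Wald 95% CIs):

1. bids on reward magnitude, starting bid, total liquid, previous
   same-magnitude competing bid and previous same-magnitude result, with
   random intercepts by trial number and session number (absorbing trial
   progression and day-to-day variability);
2. the same without reward magnitude in the fixed effects — it moves to the
   random intercepts, isolating non-magnitude drivers;
3. streak counts replacing the previous result in the fixed effects, with
   the previous result moved to the random intercepts (streaks and the
   previous result are collinear by construction).

Predictors are left in their natural units; the reported adjusted $R^2$ is
the squared correlation of fitted and observed bids adjusted for the number
of fixed effects. Near-zero random-effect variances produce singular fits —
reported as messages, distinct from genuine convergence failures, which
warn with the optimizer's diagnostics.

`bid_coherence()` interpolates each magnitude's bids linearly onto the full
session trial grid (the simplest interpolation preserving trial order) and
rank-correlates the three vectors pairwise with Spearman's rho, matching the
rank-based statistics used elsewhere; because interpolation fills trials
where a magnitude was absent, the estimate is a lower bound — even a
noise-free shared drift yields rho ≈ 0.85–0.95, not 1.

## Neuronal response analysis

Dopamine-like classification requires a wide impulse waveform (> 1.8 ms),
low baseline (< 10 Hz) and a significant response to at least one task event
(0–200 ms post event vs the pre-event baseline, paired Wilcoxon, p < .05).
The screen is implemented against the baseline rather than against zero —
an absolute test would conflate baseline rate with responsiveness.

`detect_value_window()` finds the analysis window that isolates the value
component: the *start* is where the lowest-magnitude population trace (which
carries a negative prediction error in its value component but an unchanged
initial excitation) first returns to the baseline mean after the initial
component's peak, rounded to the nearest 20 ms (a 20 ms moving average is
applied for this crossing only); the *end* is the first 20 ms bin at or
after the start where the highest-magnitude trace is no longer significantly
different from zero across neurons (two-sided sign-rank, Holm-corrected over
the 25 bins in 0–500 ms). Since the sign-rank's smallest attainable p is
$2^{1-n}$, at least 12 neurons are needed for any bin to survive Holm
correction; smaller populations fail with an explicit status, as do traces
that never return to baseline. All windowed analyses use unsmoothed counts;
smoothing exists only for display traces (100 ms default).

Windowed rates are z-normalized per neuron across its trials, so neurons
with different dynamic ranges contribute comparably to population analyses;
zero-variance neurons are excluded with a warning. The bid regression
(`bid_regression()`) is ordinary least squares of the (optionally
bin-averaged) response on the bid; `select_bid_encoding()` keeps neurons
with p < .05 *and* positive slope.

`matched_bid_comparison()` tests magnitude coding at matched subjective
value: bids within 5% of the bid space are matched one-to-one across two
magnitude levels (greedy nearest-bid matching within each session and
neuron — the pairing algorithm is not dictated by the procedure's
description, and greedy matching is deterministic and order-free),
response differences are pooled and sign-rank tested. A comparison whose
matched bid distributions differ (two-sided rank-sum, p < .05) is eliminated
before testing, since a residual bid mismatch would masquerade as a
magnitude effect. Movement controls regress responses on velocity, absement
and their unsigned variants per neuron and compare the count of significant
neurons against the 5% binomial chance level.

## Pseudo-population decoding

`build_pseudopopulation()` discretizes bids into 10 equal-width tenths (the
printed top range "[0.91–1.0]" in the source protocol is treated as a typo
for the equal-width tenth) and draws, per neuron, 10 trials per bin without
replacement — 100 balanced pseudo-trials. Neurons lacking 10 trials in any
bin are excluded by name. Each decoding iteration redraws the pseudo-trials,
then runs a 5-fold cross-validation in which folds hold out a deterministic
rotation of 2 trials per bin (8 × 10 train, 2 × 10 test). The decoder is a
linear epsilon-insensitive SVR (libsvm defaults: cost 1, epsilon 0.1;
features are the upstream z-scores, so no further scaling is applied and
results are invariant to per-neuron affine rescaling of raw rates). The
regression target is the bin midpoint (raw-bid targets are available as an
option); shuffled controls permute the targets globally across the 100
pseudo-trials before training (within-bin permutation is exposed as an
option but is a no-op for midpoint targets).

Per-fold performance is the **sign-preserving squared Pearson correlation**
between predicted and actual targets: explained variance carrying the sign
of the correlation. This definition makes chance-level decoding symmetric
around zero for any population and any regularization — the
sum-of-squares definition $1 - SS_{res}/SS_{tot}$ is dominated by the
variance of the decoder's noise predictions (chance $\approx -0.8$ with 20
features and 80 training trials), which contradicts both the flat
near-zero shuffled curves this protocol is known to produce and the
requirement that shuffled controls calibrate within $[-0.1, 0.1]$.
Below-chance (anticorrelated) predictions still read negative; constant
predictions read 0. The headline accuracy in percent clamps the
iteration-mean at zero, so shuffled controls report 0%.

`decoding_curve()` aggregates 300 iterations (the smoke profile uses 30)
per neuron count, adding neurons best-first (upper bound), worst-first
(lower bound) or randomly (the typical neuron; a fresh subset each
iteration). Real and shuffled iteration-level distributions are compared by
two-sided rank-sum.

## Problem sizes and reproducibility

Every stochastic stage derives its seed from a single master seed
(`derive_seed()`), so full pipeline runs — and the on-disk datasets written
by `generate_dataset()` — are byte-identical across runs at a fixed seed.
The package's own checks run the protocols at these sizes: incentive
compatibility on a 1001-point bid grid; chance-level decoding with 20
neurons and the full 300 iterations; regression power and false-positive
calibration over 50 seeds at 200 trials; window recovery over 50 seeds with
12-neuron populations; matched-bid discrimination over 20 seeds with
10-neuron populations; curve-ordering properties at 50 iterations; and
coherence calibration over 50 seeds. These sizes were chosen so each
property is measured with comfortable Monte-Carlo margins on a single CPU.

## Known limitations

* The generator's linear rate model with a floor is a deliberate
  simplification; real dopamine responses saturate and adapt.
* Coherence estimates are interpolation-limited lower bounds; sessions
  where a magnitude's bids are constant (e.g. all clipped at zero) have
  undefined rho and are reported as such.
* Mixed model 2 places a random intercept over only three magnitude levels;
  with so few levels the variance estimate is crude and singular fits are
  common — the fixed-effect contrasts of interest are unaffected.
* The value-window end detection needs ≥ 12 neurons (Holm-corrected
  sign-rank); single-session pilots must supply a window explicitly.
* Decoding accuracy on synthetic populations is higher than one should
  expect from real recordings: synthetic neurons share one noiseless latent
  signal, have stationary tuning, and carry no correlated noise.
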