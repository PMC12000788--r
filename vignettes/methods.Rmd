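---
title: "Methods: simulating and modelling physician sleep advice for shift workers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and modelling physician sleep advice for shift workers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the data
model and generator it simulates, the statistics and learning protocol
it implements, the numerical choices behind them, and what a green test
suite does and does not establish.

## 1. The setting and the data model

The package models a five-week observational/intervention protocol on
hospital shift workers. Each participant contributes six tables:
minute-level heart rate and step counts from a wrist-worn device;
wearable-detected sleep periods (start, end, duration, efficiency);
morning and evening surveys (sleep report, behaviours, Likert and
visual-analog well-being scales); self-reported work schedules at
30-minute resolution; and an advice log in which, from the second week
on, a physician selects 1–5 messages from a 23-message catalog and the
participant optionally responds *eager to follow* or *difficult to
follow*.

Everything downstream operates on two derived objects:

* a `day_grid` — a days × bins binary matrix per participant (1-minute
  bins for sleep/naps, 30-minute bins for work), with flagged days for
  unusable reports;
* a daily feature table — one row per participant-day holding the full
  inventory (heart-rate mean/SD/sample entropy; steps and
  segment-duration entropies; main sleep and naps; sleep regularity
  index; behaviours; work hours per period for today, yesterday and the
  day before; well-being).

### Sleep regularity index

For a window of $W$ days the SRI is
$$\mathrm{SRI} = -100 + \frac{200}{1440\,(W-1)}
  \sum_{d=1}^{W-1}\sum_{m=1}^{1440} \mathbf 1[s_{d,m} = s_{d+1,m}],$$
the linearly rescaled probability that the sleep/wake state matches at
minute pairs 24 h apart. Windows are **trailing** (anchored on their
last day): the index is used as a predictor of future advice, so it may
only look backward. A window containing a flagged day yields `NA`,
never 0. The definition is invariant to the choice of day boundary; we
use calendar midnight and split midnight-crossing periods across rows.

### Entropy features

Sample entropy uses $m = 2$ and $r = 0.2\,\mathrm{SD}$ of the day's
series (the cardiovascular-series convention; the tolerance is in beats
per minute). Matching uses the Chebyshev distance with self-matches
excluded; a constant day scores 0, and a day with no length-$m$ matches
is missing. Segment-duration entropies are Shannon entropies (natural
log) of the duration distribution of maximal active (steps > 0) and
stationary runs; missing minutes count as stationary so the run
structure is preserved.

## 2. The synthetic cohort: a stated world

No real cohort is available, so the generator *is* the world the tests
live in. Its defaults were calibrated **once** against the published
population summaries and frozen; they are not tuning knobs.

* **Shift rotation.** A first-order Markov chain over
  {off, day 8–16, afternoon 16–24, midnight 0–8}. The stationary law
  (≈ .30/.26/.25/.19) reproduces the observed mean work hours per
  8-hour period; a 0.40 diagonal persistence blend produces the
  multi-day shift blocks of real ICU rosters (and, through them, the
  observed level of day-to-day sleep regularity); the
  afternoon→midnight transition is structurally zero (the two shifts
  abut at midnight).
* **Shift-conditioned sleep.** Each (previous shift, current shift)
  context holds a truncated-normal duration (lower bound 60–90 min) and
  a wake-time anchor; onset = wake − duration. Day-then-midnight
  contexts draw short evening sleeps (target mean 220 min before the
  00:00 shift start); off-then-day contexts draw the long regime
  (~400 min). Truncated-normal locations are re-solved at configuration
  time so realized means equal their targets despite the lower bound.
  Longer-than-typical sleeps extend the wake as well as the onset
  (half-loading), so duration variance only partially becomes schedule
  irregularity. Wake times are capped at 07:55 — a generator
  simplification that keeps every main sleep inside its reporting day.
* **Naps.** A long post-midnight-shift recovery nap (p = 0.8, ~300 min)
  plus occasional short afternoon naps (Poisson rate 0.52, ~40 min),
  jointly reproducing the observed nap count (~0.56/day) and nap
  minutes (~53/day).
* **Physiology.** Heart rate is participant baseline + circadian
  sinusoid − sleep dip + AR(1) noise (φ = 0.985), calibrated to the
  observed daily mean, within-day SD, and sample-entropy level; steps
  are hour-modulated Bernoulli activity with Poisson counts calibrated
  to the observed daily total and its dispersion.
* **Physician policy.** One interpretable threshold rule per modelled
  message (bedroom brightness → message 7, pre-sleep phone use → 4,
  short sleep → 21, afternoon-shift variability → 12, caffeine
  variability → 14, low sleep satisfaction → 15, high satisfaction or
  nothing-to-flag fallback → 20), with logistic softness, a small noise
  floor, and low-probability rules populating the rarely chosen tail.
  Thresholds were calibrated once to the published marginal selection
  frequencies (message 20 ≈ half of pieces, 21 ≈ 0.28, minor modelled
  messages at negative:positive ratios of 5–15). The message-20 rule is
  deliberately sharp (logistic scale 0.22, p_max 0.95): the published
  prediction performance for that message implies physicians'
  keep-doing-what-you-do selections were highly systematic, and a
  noisier rule contradicts that printed evidence.
* **Responses.** Per-event categorical draw governed by the most
  salient selected message: difficult-to-follow probabilities are near
  zero for message 20 (0.005) and high for habit-change messages
  (message 4: 0.20, message 2: 0.26); otherwise eager vs no-response in
  a 55:30 split.
* **Missingness.** Independent per-day Bernoulli dropout of the morning
  survey (0.10), evening survey (0.10) and the wearable day (0.05),
  giving day-level completeness ≈ 0.77 — matching the published
  complete-day fraction — and exercising the downstream exclusion
  rules. Advice windows are computed by the policy on the noise-free
  truth (physicians saw the data before any loss).

**What a green test establishes.** That the implemented operators are
correct against brute-force oracles, that the protocol is leak-free, and
that in this stated world the protocol recovers planted structure. It
does **not** establish real-world effect sizes: the generator has no
circadian physiology, no adherence dynamics (advice does not change
later behaviour), independent behaviours where real ones correlate, and
block-level rather than item-level survey missingness.

## 3. Advice samples and the learning protocol

For each advice date, every retained daily feature is aggregated over
the **4 calendar days strictly before** the date as window mean and
sample SD (denominator $n-1$), joined with 23 response features (most
recent response to an earlier piece containing each message: +1 eager,
−1 difficult, 0 otherwise) and per-message binary labels. Any missing
value in the window drops the sample (exclusion, not imputation).
Structurally optional features (SRI, activity-conditional gaps) are
excluded from the model matrix by default so that their definitional
absence does not trigger the exclusion rule.

Two split modes: *user-dependent* (first 70% of each participant's
samples by date train; `floor(0.7 n)` so fractional counts favour
training) and *user-independent* (first 70% of participants by
enrollment order). Participants with fewer than two surviving samples
cannot be split chronologically and are dropped with a warning.

Three classifier families share one native CART-style learner
(variance-reduction splits, Newton leaf values):

* bagged depth-wise trees with per-node feature subsampling (leaf
  values are class fractions, so the ensemble margin is a probability);
* leaf-wise (best-first) gradient boosting with logistic loss, limited
  by `max_leaves`;
* symmetric (oblivious) gradient boosting: one shared split per depth
  level, chosen on 32-bin histograms.

Tuning is random search (study protocol: 100 draws) over
repository-defined grids, scored by mean out-of-fold AUPRC under
stratified 5-fold CV — participant-grouped folds in the independent
mode. Balancing (random oversampling or SMOTE with $k = 5$ neighbours,
adaptively reduced) is applied **inside training folds only**;
validation folds keep the original class ratio, a leak-free choice the
protocol description leaves open. All randomness derives from the run
seed through fixed offsets.

## 4. Evaluation and explanation

AUPRC is the step-wise average-precision estimator over decreasing score
thresholds; tied scores form one threshold group, so constant scores
give exactly the prevalence (trapezoidal interpolation would differ at
these sample sizes). Per configuration the tuning/training is repeated
over seeds (10 in the full protocol); the seed sample is compared to
uniform-random score baselines with a one-sided Welch $t$ test
(Welch–Satterthwaite degrees of freedom; an exact tie of two
zero-variance samples returns $P = 0.5$ by convention).

Decision thresholds maximise F1 over a grid of 101 points in $[0,1]$ on
pooled out-of-fold scores (ties → lowest threshold); the deployed
predictor is a majority vote of an odd number of per-seed thresholded
classifiers (9 of the 10 seeds in the full protocol) and is compared to
the always-positive baseline $F_1 = 2p/(1+p)$.

Importance combines 10-repeat permutation AUPRC decrease on the test
set (permutation seeds derive from the run seed offset by feature
index) with path-dependent TreeSHAP. Shapley values are computed in
each model's **native margin space** — probability for bagged forests,
log-odds for the boosted families — because that is the space in which
tree-path attributions are exactly additive
(`base value + Σ φ = margin(x)`); asserting additivity against
logistic-transformed probabilities would be false by construction for
boosted models. A feature is *reported* when it ranks in the top 5 by
both measures and both means clear 0.01.

## 5. Numerical and design choices

* Ward clustering uses `stats::hclust(method = "ward.D2")` on Euclidean
  distances of z-scored features; the test oracle is an independent
  greedy merger with explicit cluster statistics. The primary
  dendrogram cut is 0.7 × the maximum merge height (the common
  colour-threshold default); cluster labels are renumbered by leaf
  order so they are deterministic.
* PCA retains the smallest component count reaching 95% cumulative
  variance; t-SNE (perplexity 30 by default, fixed seed) runs on those
  scores.
* Generator calibration checks use **participant-clustered** standard
  errors (`sd` of participant means / √participants): days within a
  participant are correlated, and the naive day-level SE would
  understate the sampling variability of the cohort mean.
* Desk-scale acceptance runs (~30 participants, 3 seeds, reduced
  random-search budget) shrink the compute, not the protocol: the same
  CV structure, leak rules, baselines and reporting rules apply.
* Degenerate inputs: single-class training labels error; single-class
  CV validation folds are re-drawn once, then error; SMOTE falls back
  to random oversampling for singleton minorities; empty oblivious-tree
  children inherit the parent value with an ε cover so SHAP cover
  ratios stay finite.

## 6. Known limitations

* The physician policy is an explicit stand-in; feature-importance
  recovery in this world shows the protocol *can* surface true drivers,
  not that real physicians follow threshold rules.
* Advice has no effect on subsequent behaviour in the generator, so
  personalization dynamics (e.g., learning from responses over time)
  are only shallowly represented through the response features.
* The wearable is nearly honest (small timing noise); real devices
  mis-score sleep in ways that interact with shift work.
* Oblivious-tree histograms (32 bins) trade exactness of split search
  for speed; the depth-wise and leaf-wise learners scan exact
  thresholds.
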