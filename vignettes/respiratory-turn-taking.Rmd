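---
title: "Methods: from lung-volume traces to turn-taking statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from lung-volume traces to turn-taking statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(breathturn)
```

This vignette documents the models and procedures implemented in
`breathturn`, the assumptions behind them, the numerical choices that
matter, and the design decisions that were genuinely open. It states no
empirical result beyond what the package's tests and acceptance script
compute themselves.

## The measurement model

The input is one uniformly sampled lung-volume proxy per speaker — the
weighted sum of rib-cage and abdomen belt signals from respiratory
inductance plethysmography (RIP) — plus per-speaker speech-activity
intervals (and optionally laughter intervals). The signal is in
arbitrary units with an arbitrary, slowly drifting baseline, which
motivates the two-stage normalisation:

* **z-scoring per speaker over the whole conversation.** Segmentation
  thresholds are defined in standard deviations of the speaker's own
  signal, so belt gain does not matter. Whole-conversation scope (as
  opposed to windowed scope) keeps the transformation affine and
  monotone; drift is handled later by the dynamic baseline, not here.
* **Speaking volume (SV).** The 5th–95th percentile span of all cycle
  landmark values (peaks and troughs pooled, shared troughs counted
  once). Amplitudes expressed in SV units are comparable across
  speakers with different vital capacities and belt tensions.
  Percentiles use linear interpolation between order statistics
  (`stats::quantile()` type 7, the most common convention; the type is
  configurable).
* **Resting expiratory level (REL).** The median trough value within a
  60-s window, evaluated at every trough and interpolated linearly in
  between. The window is *centred* by default; a trailing window is
  available (`rel_align = "trailing"`) for strictly causal processing.
  REL maps to 0 in SV units, so a level of 0.3 reads as "30% of the
  speaking volume above resting level". An empty window falls back to
  the global trough median with a warning.

### Cycle segmentation

Breathing cycles are trough–peak–trough triples found on the z-scored
signal. The landmark search keeps strict local extrema (the first
sample of a flat extremum is the landmark), then greedily prunes the
sequence so that retained landmarks strictly alternate and every
adjacent peak–trough pair differs by at least `min_sep_sd` (default 1
standard deviation). The pruning is implemented as a single
hysteresis scan that tracks the running extreme of the current phase
and emits a reversal only once the signal has moved by `min_sep_sd`;
the test suite verifies on hundreds of random piecewise-linear signals
that this is equivalent to exhaustive extremum enumeration followed by
smallest-pair-first prominence pruning.

Two numerical refinements matter on noisy data:

* the landmark *search* runs on a lightly smoothed copy of the trace
  (`segment_smooth_ms`, default 100 ms moving average), because raw
  argmin/argmax under sensor noise wanders along the shallow slopes
  around quiet-breathing extrema;
* each landmark *time* is then refined by a two-segment least-squares
  corner fit in a ±0.4-s window (`refine_landmarks`): for every
  candidate split point, straight lines are fitted to the left and
  right parts and the split with the smallest total residual wins.
  Under white noise this is the maximum-likelihood corner location,
  and unlike wider smoothing it does not displace corners whose two
  slopes differ.

### Breath-hold detection

A hold is a plateau in the trace. Per cycle, the signal's value
histogram (100 equal-width bins over the cycle's range) is scanned for
a prominent mode — a bin whose count is at least 3× the median bin
count — and holds are maximal runs of samples within ±2.5% of the
cycle's exhalation amplitude around the mode level. Runs separated by
less than 150 ms are merged; runs shorter than 250 ms are dropped;
runs are assigned to the exhalation when at least half their duration
falls after the peak. Three robustness choices:

* the cycle's samples are smoothed with a 100-ms moving average before
  histogramming and run detection (`smooth_ms`); without it, noise at
  2% of the breathing amplitude spreads plateau samples across several
  bins and fragments runs, and 300-ms holds drop below the prominence
  threshold;
* runs are trimmed away from a 250-ms neighbourhood of the cycle peak
  and offset trough (`landmark_margin_s`): a rounded extremum dwells
  inside the margin band for up to roughly the minimum hold duration
  and is indistinguishable from a brief plateau there;
* since speech itself produces slowly decaying quasi-plateaus, only
  hold candidates that do not overlap the speaker's own talkspurts are
  retained (`filter_silent_holds()`). No spectral speech check is
  attempted — the silent-exhalation restriction is the only guard.

## The interactional model

Talkspurts are maximal stretches of one speaker's voice activity with
internal pauses shorter than 200 ms (`min_pause_s`); talkspurts shorter
than 1 s count as backchannels. Interactional intervals are classified
by two criteria — overlap and speaker change — into WSS, WSO, BSS and
BSO. Concretely, silence events are the maximal gaps in the union of
all speakers' talkspurts, bounded by the talkspurt ending at the gap
start and the one starting at the gap end; overlap events are computed
pairwise, distinguishing contained overlaps (WSO — the floor stays
with the outer speaker) from overlapped transitions (BSO). This
union-based formulation reproduces offset-to-next-onset anchoring for
all non-nested configurations while avoiding nonsensical silence spans
when a backchannel is nested inside a longer talkspurt. Ties at exactly
coincident boundaries break toward the longer talkspurt. All intervals
are half-open `[start, end)` in seconds.

WSS, BSS and BSO events are augmented with the previous speaker's
inhalation status: **+INH** when an inhalation onset falls strictly
between the anchoring talkspurt offset and that speaker's next
talkspurt onset, **−INH** when the next own talkspurt continues the
same exhalation. An inhalation already in progress at a talkspurt edge
is not +INH; it triggers the `edge_inhalation` exclusion instead.
Events whose previous speaker never speaks again get `inh = "na"` and
are excluded.

Exclusions are applied in a fixed order (first match wins):
`edge_inhalation`, `laughter` (any positive temporal intersection of
the event span or its bounding talkspurts with a laughter interval),
`backchannel` (either bounding talkspurt shorter than 1 s), and
`missed_inhalation_suspect` — a −INH event whose anchoring exhalation
lasts more than twice the speaker's median cycle duration. The last
rule is an automatic proxy for a manual plausibility check: the
segmentation occasionally misses a small inhalation, which silently
fuses two cycles into one implausibly long "exhalation"; such events
are flagged and excluded by default rather than hand-checked.

Turn-initial (TT) events are talkspurts whose onset either overlaps
another speaker's talkspurt (TT(O)) or follows silence with the most
recent talkspurt belonging to someone else (TT(S)); each links the
incoming speaker's immediately preceding inhalation, and talkspurts
that do not start during their own cycle's exhalation produce no TT
event.

## Features and exclusion of extreme slopes

For every non-excluded event the anchoring exhalation yields amplitude
(SV), duration (log₂ s), slope (−amplitude/duration, SV/s, negative),
onset and offset levels (SV, REL = 0 at the landmark's own time, i.e.
dynamic REL), and hold presence. Linked inhalations yield duration,
amplitude, slope (positive), offset level and — where the same speaker
continues or initiates (WSS+INH, TT(S), TT(O)) — the speech lag,
log₂(speech onset − inhalation onset). Durations are floored at one
sample period before the logarithm. The inhalatory slope divides
amplitude by the inhalation duration by default; a configuration
switch (`slope_denominator = "speech_lag"`) divides by the speech lag
instead, for the subset where the lag is defined — the lag-based
definition cannot cover between-speaker +INH intervals, which is why
duration is the default.

Rows whose inhalatory or exhalatory slope lies at least 3 SD from the
mean (computed separately per slope type, pooled across speakers) are
marked `extreme_slope` and excluded. With zero SD nothing is excluded.

## Hidden events

Two quantities target turn-taking intentions invisible to silence-based
representations:

* **P(speaker change | hold)** vs **P(speaker change | no hold)** over
  all non-excluded silence events (WSS ∪ BSS), where hold co-occurrence
  means a silent-exhalation hold overlapping the anchoring exhalation
  (holds are exhalation-bound by construction, so the exhalation, not
  the silence span, is the right anchor). Empty strata report `NA`.
  The weighted average of the two probabilities equals the marginal
  speaker-change rate exactly — an identity the test suite asserts on
  every simulated corpus.
* **Abandoned initiation candidates**: holds within the top 20% of the
  exhalation *amplitude* (not time) of cycles free of the speaker's own
  speech — a participant inhales, holds their breath as if to speak,
  then exhales silently. These candidates, the remaining silent cycles
  and the pre-speech TT(S) inhalations form the three-group table for
  the silent-cycle model.

## The multinomial engine

`fit_multinomial()` fits a baseline-category multinomial logit by
full Newton–Raphson: analytic gradient and block Hessian, step halving
on the log-likelihood, convergence when the log-likelihood changes by
less than 1e-8, at most 100 iterations. The reference level carries no
coefficients. Wald 95% intervals and p-values come from the inverse
observed information. McFadden's pseudo-R² is 1 − LL/LL₀ with LL₀ the
intercept-only likelihood (closed form: category proportions). Degenerate
inputs fail loudly: rank-deficient designs are reported with the
collinear column names, and perfect separation (likelihood at the
no-information bound with diverging coefficients) raises a
non-convergence error rather than returning meaningless estimates.
The test suite checks the fitter against a closed-form 2×2 log odds
ratio to 1e-6, an independent `optim()`-based maximum-likelihood
oracle to 1e-4, and `nnet::multinom()`.

Stepwise selection adds candidate predictors one at a time in a stated
order, keeping a predictor when 2·(LL₁ − LL₀) exceeds the χ² critical
value at α = 0.05 with degrees of freedom equal to the number of
coefficients added. A candidate linearly dependent on the current
design cannot change the likelihood and is rejected outright.
Collinearity among duration, amplitude and slope (and between onset
and offset levels) is handled declaratively, not by automatic VIF
pruning: each block is represented by a designated predictor (slope;
offset level), which keeps the model specification reproducible.

Four model families are pre-registered in `mnl_config()`: the
exhalatory model over the six augmented categories (slope, offset
level, hold presence; reference WSS−INH, the unambiguously
turn-holding category), the inhalatory model over all
inhalation-bearing categories (slope, offset level; reference
WSS+INH), the turn-taking inhalatory model (adding speech lag over
WSS+INH, TT(O), TT(S)) and the silent-cycle model (inhalation
amplitude and duration over Silent/Hold/TT(S); reference Hold).
`fit_family()` drops outcome levels with fewer than 5 rows before
fitting — with one or two observations a level's coefficients are
unidentifiable and the iterations walk into quasi-separation.

## The conversation simulator

`simulate_conversation()` exists so that every stage of the pipeline is
testable against known ground truth. It emulates:

* a semi-Markov floor process: turns of one to four talkspurts
  (continuation probability 0.62), speaker changes with overlap
  probability 0.33, gaps around 0.45 s, occasional backchannels and
  laughter;
* within-turn continuations either on the same exhalation (−INH, with
  a pause riding the ongoing exhalation) or after a short inhalation
  (+INH); at most one same-exhalation continuation before an
  inhalation is forced, keeping −INH exhalation durations plausible;
* pause interruptions: another speaker interjects a single talkspurt
  while the original speaker's exhalation continues through the
  silence, realising BSS−INH/BSO−INH events;
* speech-breathing asymmetry: fast, deep pre-speech inhalations over
  long speech exhalations versus more symmetric quiet cycles, with
  within-turn inhalations shorter and quicker into speech than
  turn-initial ones (the temporal-compression pattern);
* plateau holds planted as exactly flat segments: per-category rates
  on anchoring exhalations (a few percent, highest for −INH
  between-speaker intervals), and on 8% of quiet cycles with a bimodal
  amplitude position (a quarter near the top of the exhalation —
  abandoned-initiation-like, the rest near the bottom). Cycles
  receiving a top hold get a modestly longer, deeper inhalation;
* rendering as piecewise-linear breakpoints with raised-cosine corner
  smoothing (60-ms Hann kernel) plus white sensor noise, default SD 2%
  of the mean cycle amplitude.

Silent (non-speech) segments of speech exhalations keep a minimum
descent slope of 0.2 amplitudes per second, because a slower silent
exhalation is genuinely indistinguishable from a plateau at the
detector's margins — planted "no-hold" ground truth must not mimic
holds. Planted cycle geometry likewise respects the segmentation
assumptions (inhalation and exhalation amplitudes at least ~1.5
standard deviations), since ground truth that violates the signal
model's own preconditions is unrecoverable by construction.

What the simulator does *not* emulate — and hence what passing tests
do **not** establish about real recordings: belt slippage and other
non-stationary artefacts, baseline drift beyond the jittered REL,
speech-induced quasi-plateaus with realistic spectral structure,
laughter breathing, inhalation noises, or any correlation structure in
the sensor noise. Recovery scores on simulated data are upper bounds
for corpus performance; corpus-level claims require the deposited
recordings (see `?reproduce_corpus`).

## Problem sizes and determinism

The test suite exercises oracle equivalence on 100 random instances
per elementary operation, label recovery on full 20-minute three-party
simulations (one noisy at 2% amplitude noise, one noiseless), the
statistical benchmarks on n = 2000 simulated multinomial draws (10
replicates) and 100 stepwise null replicates, and the
total-probability identity on several 4–5-minute corpora. The
acceptance script pools six 20-minute conversations. All simulations
are seeded; a single root seed makes traces, tables and labels
bit-reproducible (per-speaker sub-streams were considered and
rejected — one stream is simpler and equally reproducible since the
generation order is deterministic).

## Known limitations

* The multiparty chronogram resolves three-way simultaneous starts by
  the longer-talkspurt tie-break; other conventions are defensible and
  would relabel a handful of events in dense overlap.
* The missed-inhalation proxy (2× median cycle duration) trades a
  manual check for a deterministic rule; it will occasionally discard
  genuine marathon exhalations and keep fused cycles just under the
  threshold.
* Hold detection near cycle landmarks is deliberately conservative
  (the 250-ms corner shadow): a real hold beginning at the very peak
  instant is shortened or, if brief, missed.
* Wald intervals are used throughout, matching symmetric reporting
  conventions; profile-likelihood intervals are out of scope.
* REL and SV assume the belts are not re-tensioned mid-conversation;
  re-calibration events should be handled by splitting the recording.
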