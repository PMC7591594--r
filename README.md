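# breathturn

Respiratory turn-taking analysis for multiparty conversation in R.

## What this is for

In casual conversation, speakers manage the floor partly with their
breathing: they inhale before claiming a turn, keep an exhalation going
through a pause they intend to resume after, and sometimes hold their
breath outright. `breathturn` turns raw lung-volume recordings
(respiratory inductance plethysmography, RIP — the weighted-sum belt
signal) and speech-activity annotations into a quantitative account of
these behaviours. It is aimed at phoneticians and interaction
researchers working with multi-speaker breathing corpora, and at
developers of spoken dialogue systems who need turn-taking cues beyond
silence detection.

The pipeline:

1. **Signal core** — each speaker's trace is resampled to a uniform
   working rate, z-scored over the conversation, and segmented into
   breathing cycles at peaks and troughs separated by at least one
   standard deviation. Amplitudes are calibrated into *speaking volume*
   (SV) units — the 5th–95th percentile span of all landmark values —
   and levels are referenced to the dynamic *resting expiratory level*
   (REL), the median trough value in a sliding 60-s window.
2. **Breath holds** — plateaus in the trace, found per cycle as dwell
   around a prominent mode of the cycle's value histogram (minimum
   duration 250 ms, minimum gap 150 ms), restricted to silent
   exhalations.
3. **Chronogram** — talkspurts (interpausal units, 200-ms pause
   threshold) are classified into within/between-speaker silences and
   overlaps (WSS, WSO, BSS, BSO), each augmented by whether the previous
   speaker inhales before their own next talkspurt (+INH) or continues
   on the same exhalation (−INH). Turn-initial talkspurts are classified
   as TT(S) or TT(O) by whether they follow silence or overlap.
   Backchannels (talkspurts < 1 s), laughter, inhalation-straddling
   edges and implausibly long −INH exhalations are excluded.
4. **Features** — per interval: exhalation amplitude (SV), duration
   (log₂ s), slope (SV/s), onset/offset levels (SV, REL = 0), hold
   presence; and for the linked inhalation: duration, amplitude, slope,
   offset level and speech lag.
5. **Hidden events** — the probability of a speaker change conditioned
   on a respiratory hold, P(change | hold) vs P(change | no hold), and
   *abandoned turn initiations*: holds in the top 20% of a silent
   exhalation's amplitude.
6. **Models** — baseline-category multinomial logistic regression
   (Newton–Raphson, in-package) with stepwise −2·log-likelihood
   predictor selection and McFadden's pseudo-R² = 1 − LL/LL₀.

A ground-truth conversation simulator (`simulate_conversation()`)
generates three-party conversations with planted cycles, holds and
labels so every stage can be validated without corpus data.

## Worked example

```r
library(breathturn)

sim <- simulate_conversation(sim_config(), seed = 42)
sim
#> <breathturn_sim> 3 speakers, 1200 s, 432 talkspurts, 963 cycles, 68 planted holds

res <- analyze_conversation(sim$traces, sim$intervals, sim$laughter)

res$hold_condition
#> Speaker change conditioned on respiratory hold
#>   with hold:    P(change) = 0.625  (10 / 16)
#>   without hold: P(change) = 0.441  (130 / 295)

summary(res$models$exhalatory$fit)
#> Multinomial logit (reference: WSS-INH), n = 337
#>    level        predictor       B   exp_B  ci_low ci_high       p
#>  WSS+INH      (Intercept)   0.273   1.314  -0.728   1.274 5.9e-01
#>  WSS+INH        exh_slope  -3.682   0.025  -8.129   0.764 1.0e-01
#>  WSS+INH exh_offset_level -12.862   0.000 -18.926  -6.798 3.2e-05
#>  BSS+INH      (Intercept)  -2.889   0.056  -3.989  -1.788 2.7e-07
#>  BSS+INH        exh_slope -13.497   0.000 -17.956  -9.039 3.0e-09
#>  BSS+INH exh_offset_level   5.929 375.593   3.259   8.598 1.3e-05
#>  BSO+INH      (Intercept)  -4.080   0.017  -5.594  -2.567 1.3e-07
#>  BSO+INH        exh_slope -12.399   0.000 -17.641  -7.157 3.6e-06
#>  BSO+INH exh_offset_level   6.012 408.412   2.190   9.835 2.1e-03
#> logLik -357.479 (null -432.458), McFadden R2 = 0.1734

nrow(res$candidates)   # abandoned turn initiations
#> [1] 13

pipeline_recovery_report(sim, res)
#> Pipeline recovery against simulation ground truth
#>   cycle landmarks: precision 0.999, recall 0.999
#>   holds (>= min duration): P 0.940, R 0.926, F1 0.933 (68 planted, 67 detected)
#>   abandoned candidates: P 1.000, R 1.000 (13 planted)
#>   +/-INH agreement 1.000, TT label agreement 1.000, events matched 1.000
#>   exhalatory-model max |coef diff| 1.31
```

Reading the output: a speaker change is markedly more likely when the
silence co-occurs with a respiratory hold (0.625 vs 0.441) — holds in
this simulated corpus behave reactively, as a response to incoming
speech, not as a turn-holding signal. In the exhalatory model, +INH
categories differ from the turn-holding WSS−INH reference: ending the
exhalation lower (near REL) and with a steeper slope raises the odds of
an inhalation-preceded continuation, while speaker-change categories
(BSS+INH, BSO+INH) additionally show positive offset-level effects on
this run's calibrated scale. The recovery report confirms the pipeline
recovered essentially all planted cycles, holds and labels.

File-based workflows use `conversation_bundle()` + `run_pipeline()`,
which read WAV/TextGrid/TSV inputs and write one TSV per stage plus a
JSON run manifest; `write_sim()` emits a simulated conversation in the
same formats. The full tunable-parameter set is documented in
`default_config()` and the shipped YAML template
(`system.file("extdata", "default_config.yaml", package = "breathturn")`).

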