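# breathturn pipeline configuration (full default template)

working_rate_hz: 100     # uniform resampling rate before segmentation (Hz)
min_sep_sd: 1.0          # minimum peak-trough separation (z units)
segment_smooth_ms: 100   # moving average before the landmark search (ms)
refine_landmarks: true   # two-segment corner refinement of landmark times
rel_window_s: 60         # REL median window (s)
rel_align: centred       # centred | trailing
quantile_type: 7         # SV percentile convention (stats::quantile type)

min_hold_s: 0.25         # minimum breath-hold duration (s)
min_gap_s: 0.15          # minimum gap between holds (s)
margin_frac: 0.025       # hold margin, fraction of exhalation amplitude
n_bins: 100              # histogram bins per cycle
prominence_ratio: 3      # mode prominence over the median bin count
smooth_ms: 100           # smoothing before hold detection (ms)

min_pause_s: 0.2         # talkspurt merging threshold (s)
backchannel_s: 1.0       # backchannel duration threshold (s)

top_amp_frac: 0.2        # abandoned-initiation amplitude cut
slope_sd_k: 3            # extreme-slope exclusion (SDs from the mean)
slope_denominator: duration   # duration | speech_lag

alpha: 0.05              # stepwise likelihood-ratio significance level
fit_models: true
stepwise: true
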