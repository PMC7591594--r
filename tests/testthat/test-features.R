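# small fully specified scene: A talks, pauses with an inhalation, talks
# again; B takes the turn later
feature_scene <- function() {
  ts <- merge_talkspurts(data.frame(
    speaker = c("A", "A", "B"),
    t_start = c(0, 4.4, 9.4),
    t_end = c(2, 6.4, 11.4)))
  cyc <- rbind(
    make_cycles(c(-1, 3.3), c(-0.5, 4.1), c(3.3, 7.4),
                v_onset = c(0, 0.2), v_peak = c(0.8, 0.9),
                v_offset = c(0.2, 0.05), speaker = "A"),
    make_cycles(8.0, 8.9, 12.0, v_onset = 0.1, v_peak = 1.0,
                v_offset = 0.0, speaker = "B"))
  cyc$cycle <- c(1:2, 1)
  ev <- apply_exclusions(augment_inh(classify_intervals(ts), cyc, ts),
                         ts, cyc)
  list(ts = ts, cyc = cyc, ev = ev,
       tt = tt_events(ts, cyc),
       holds = data.frame(speaker = character(), cycle = integer(),
                          t_start = numeric(), t_end = numeric(),
                          level = numeric(), during_silence = logical()))
}

test_that("exhalatory features follow their definitions", {
  sc <- feature_scene()
  ev <- exhalation_features(sc$ev, sc$cyc, sc$holds)
  wss <- ev[ev$base == "WSS", ]
  # anchoring exhalation: cycle 1 of A, [-0.5, 3.3], onset 0.8, offset 0.2
  expect_equal(wss$exh_amplitude, 0.6)
  expect_equal(wss$exh_duration_log2s, log2(3.8))
  expect_equal(wss$exh_slope, -0.6 / 3.8)
  expect_equal(wss$exh_onset_level, 0.8)
  expect_equal(wss$exh_offset_level, 0.2)
  # a 2-s exhalation from 0.8 to 0.2 gives the textbook numbers
  cyc2 <- make_cycles(-1, 0, 2, 0, 0.8, 0.2, speaker = "A")
  ts2 <- merge_talkspurts(data.frame(speaker = c("A", "A"),
                                     t_start = c(-1.2, 3), t_end = c(-0.2, 4)))
  ev2 <- data.frame(event = 1L, base = "WSS", inh = "minus",
                    prev_speaker = "A", next_speaker = "A",
                    t_start = -0.2, t_end = 3, prev_ts = 1L, next_ts = 2L,
                    excluded = NA_character_, next_own_onset = 3,
                    inh_cycle = NA_integer_, anchor_cycle = 1L)
  f2 <- exhalation_features(ev2, cyc2, sc$holds)
  expect_equal(f2$exh_amplitude, 0.6)
  expect_equal(f2$exh_duration_log2s, 1)
  expect_equal(f2$exh_slope, -0.3)
})

test_that("inhalatory features follow their definitions", {
  sc <- feature_scene()
  ev <- inhalation_features(sc$ev, sc$cyc, sc$ts)
  wss <- ev[ev$base == "WSS", ]
  # linked inhalation: cycle 2 of A, [3.3, 4.1], 0.2 -> 0.9
  expect_equal(wss$inh_duration_log2s, log2(0.8))
  expect_equal(wss$inh_amplitude, 0.7)
  expect_equal(wss$inh_offset_level, 0.9)
  expect_equal(wss$inh_slope, 0.7 / 0.8)
  # speech lag: next own onset 4.4 minus inhalation onset 3.3
  expect_equal(wss$speech_lag_log2s, log2(1.1))
  # a 0.5 s, 0.5 SV inhalation has duration log2 = -1 and slope 1
  cycq <- make_cycles(0, 0.5, 3, 0, 0.5, 0, speaker = "Q")
  ttq <- data.frame(kind = "TT(S)", speaker = "Q", ts = 1L, t_start = 1.5,
                    inh_cycle = 1L, excluded = NA_character_)
  fq <- inhalation_features(ttq, cycq, NULL)
  expect_equal(fq$inh_duration_log2s, -1)
  expect_equal(fq$inh_slope, 1)
  # speech onset 1 s after inhalation onset -> lag log2 = 0
  ttq2 <- ttq; ttq2$t_start <- 1.0
  expect_equal(inhalation_features(ttq2, cycq, NULL)$speech_lag_log2s, 0)
  # the speech-lag denominator option reproduces the amplitude-over-lag slope
  fq2 <- inhalation_features(ttq2, cycq, NULL, slope_denominator = "speech_lag")
  expect_equal(fq2$inh_slope, 0.5 / 1.0)
})

test_that("the shared landmark ties exhalation offset to inhalation onset", {
  sim <- simulate_conversation(sim_config(duration_s = 240), seed = 14)
  res <- analyze_conversation(sim$traces, sim$intervals, sim$laughter,
                              default_config(fit_models = FALSE))
  ev <- res$events
  plus <- ev[!is.na(ev$inh) & ev$inh == "plus" & !is.na(ev$anchor_cycle) &
               !is.na(ev$inh_cycle), ]
  for (i in seq_len(nrow(plus))) {
    sp <- plus$prev_speaker[i]
    exh <- res$cycles[res$cycles$speaker == sp &
                        res$cycles$cycle == plus$anchor_cycle[i], ]
    inh <- res$cycles[res$cycles$speaker == sp &
                        res$cycles$cycle == plus$inh_cycle[i], ]
    # when the linked inhalation directly follows the anchoring exhalation
    if (nrow(exh) == 1 && nrow(inh) == 1 &&
        abs(inh$t_onset - exh$t_offset) < 1e-9) {
      expect_equal(inh$v_onset, exh$v_offset)
    }
  }
  # slope signs over all valid feature rows
  f <- res$features
  expect_true(all(f$exh_slope[!is.na(f$exh_slope)] < 0))
  expect_true(all(f$inh_slope[!is.na(f$inh_slope)] > 0))
})

test_that("feature extraction commutes with shifting the whole conversation", {
  sc <- feature_scene()
  shift <- 100
  ts_s <- sc$ts; ts_s$t_start <- ts_s$t_start + shift
  ts_s$t_end <- ts_s$t_end + shift
  cyc_s <- sc$cyc
  for (col in c("t_onset", "t_peak", "t_offset")) {
    cyc_s[[col]] <- cyc_s[[col]] + shift
  }
  ev_s <- apply_exclusions(augment_inh(classify_intervals(ts_s), cyc_s, ts_s),
                           ts_s, cyc_s)
  f0 <- feature_table(sc$ev, sc$tt, sc$cyc, sc$ts, sc$holds)
  f1 <- feature_table(ev_s, tt_events(ts_s, cyc_s), cyc_s, ts_s, sc$holds)
  num <- vapply(f0, is.numeric, logical(1))
  expect_equal(f1[, num], f0[, num], tolerance = 1e-12)
})

test_that("the extreme-slope filter flags exactly the planted outlier", {
  set.seed(15)
  n <- 100
  f <- data.frame(id = paste0("r", 1:(n + 1)),
                  category = "WSS-INH", speaker = "A",
                  exh_amplitude = 1, exh_duration_log2s = 0,
                  exh_slope = c(rnorm(n, -0.3, 0.05), -0.3 - 10 * 0.05),
                  exh_onset_level = 1, exh_offset_level = 0,
                  hold_present = FALSE,
                  inh_duration_log2s = NA_real_, inh_amplitude = NA_real_,
                  inh_slope = NA_real_, inh_offset_level = NA_real_,
                  speech_lag_log2s = NA_real_,
                  excluded = NA_character_, stringsAsFactors = FALSE)
  # make the outlier exactly 10 sample SDs from the sample mean
  f$exh_slope[n + 1] <- mean(f$exh_slope[1:n]) - 10 * sd(f$exh_slope[1:n])
  out <- flag_extreme_slopes(f)
  expect_identical(which(out$excluded == "extreme_slope"), as.integer(n + 1))
  # equal slopes: zero SD convention -> nothing excluded
  f2 <- f; f2$exh_slope <- -0.3
  expect_true(all(is.na(flag_extreme_slopes(f2)$excluded)))
  # idempotence on the filtered table with recompute = FALSE
  flt <- out[is.na(out$excluded), ]
  attr(flt, "slope_stats") <- attr(out, "slope_stats")
  again <- flag_extreme_slopes(flt, recompute = FALSE)
  expect_true(all(is.na(again$excluded)))
})
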