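test_that("hold positions map the exhalation geometry to [0, 1]", {
  cyc <- make_cycles(0, 2, 6, v_onset = 0, v_peak = 1, v_offset = 0.2)
  holds <- data.frame(speaker = "a", cycle = 1L,
                      t_start = c(2, 5.5, 4), t_end = c(2.4, 6, 4.4),
                      level = c(1, 0.2, 0.6), during_silence = TRUE)
  hp <- hold_position(holds, cyc)
  expect_equal(hp$rel_time_pos, c(0, 0.875, 0.5))
  expect_equal(hp$rel_amp_pos, c(0, 1, 0.5))
  # zero-amplitude exhalation is a data error
  bad <- make_cycles(0, 2, 6, 0, 1, 1)
  expect_error(hold_position(holds, bad), "zero-amplitude")
})

test_that("planted hold positions are recovered through the pipeline", {
  sim <- simulate_conversation(sim_config(duration_s = 300), seed = 16)
  res <- analyze_conversation(sim$traces, sim$intervals, sim$laughter,
                              default_config(fit_models = FALSE))
  hp <- hold_position(res$holds, res$cycles)
  gt <- sim$ground_truth$holds
  for (i in seq_len(nrow(hp))) {
    g <- gt[gt$speaker == hp$speaker[i] &
              abs(gt$t_start - hp$t_start[i]) < 0.4, ]
    if (nrow(g) != 1) next
    gcyc <- sim$ground_truth$cycles
    gpos <- hold_position(g, gcyc)
    expect_lt(abs(hp$rel_amp_pos[i] - gpos$rel_amp_pos), 0.12)
  }
})

test_that("abandoned candidates are the top-of-exhalation silent holds", {
  cyc <- rbind(make_cycles(0, 2, 6, 0, 1, 0, silent = TRUE),
               make_cycles(6, 8, 12, 0, 1, 0, silent = TRUE),
               make_cycles(12, 14, 18, 0, 1, 0, silent = FALSE))
  cyc$cycle <- 1:3
  holds <- data.frame(speaker = "a", cycle = c(1L, 2L, 3L),
                      t_start = c(2.3, 9, 14.3), t_end = c(2.9, 9.6, 14.9),
                      level = c(0.9, 0.5, 0.9), during_silence = TRUE)
  cand <- abandoned_candidates(cyc, holds)
  # hold at rel_amp 0.1 in a silent cycle qualifies; 0.5 does not;
  # top hold in a speech cycle does not
  expect_identical(cand$cycle, 1L)
  expect_true(all(cand$rel_amp_pos <= 0.2))
})

test_that("speaker-change probabilities equal a direct counting oracle", {
  set.seed(17)
  # synthetic event table with a planted joint distribution
  n <- 1000
  change <- runif(n) < 0.4
  hold <- runif(n) < ifelse(change, 0.3, 0.05)
  cyc <- make_cycles(t_onset = seq(0, by = 10, length.out = n),
                     t_peak = seq(2, by = 10, length.out = n),
                     t_offset = seq(8, by = 10, length.out = n),
                     v_onset = 0, v_peak = 1, v_offset = 0, speaker = "A")
  ev <- data.frame(event = seq_len(n),
                   base = ifelse(change, "BSS", "WSS"),
                   inh = "plus", prev_speaker = "A",
                   next_speaker = ifelse(change, "B", "A"),
                   t_start = cyc$t_peak + 1, t_end = cyc$t_peak + 2,
                   prev_ts = NA_integer_, next_ts = NA_integer_,
                   excluded = NA_character_, next_own_onset = NA_real_,
                   inh_cycle = NA_integer_, anchor_cycle = seq_len(n))
  holds <- data.frame(speaker = "A", cycle = which(hold),
                      t_start = cyc$t_peak[hold] + 0.5,
                      t_end = cyc$t_peak[hold] + 1.0,
                      level = 0.5, during_silence = TRUE)
  hc <- speaker_change_given_hold(ev, holds, cyc)
  expect_identical(hc$n_silence_with_hold, sum(hold))
  expect_equal(hc$p_change_given_hold, sum(change & hold) / sum(hold))
  expect_equal(hc$p_change_given_no_hold, sum(change & !hold) / sum(!hold))
  # recovered probabilities sit inside a generous binomial band
  expect_lt(abs(hc$p_change_given_hold -
                  0.4 * 0.3 / (0.4 * 0.3 + 0.6 * 0.05)),
            4 * sqrt(0.25 / sum(hold)))
  # degenerate strata
  hc0 <- speaker_change_given_hold(ev, holds[0, ], cyc)
  expect_true(is.na(hc0$p_change_given_hold))
  ev_all_change <- ev; ev_all_change$base <- "BSS"
  hc1 <- speaker_change_given_hold(ev_all_change, holds, cyc)
  expect_equal(hc1$p_change_given_hold, 1)
  expect_equal(hc1$p_change_given_no_hold, 1)
})

test_that("the law of total probability holds exactly", {
  for (seed in c(18, 19, 20)) {
    sim <- simulate_conversation(sim_config(duration_s = 240), seed = seed)
    res <- analyze_conversation(sim$traces, sim$intervals, sim$laughter,
                                default_config(fit_models = FALSE))
    hc <- res$hold_condition
    n <- hc$n_silence_with_hold + hc$n_silence_without_hold
    p_marg <- (hc$n_change_with_hold + hc$n_change_without_hold) / n
    w <- c(hc$n_silence_with_hold, hc$n_silence_without_hold) / n
    p <- c(hc$p_change_given_hold, hc$p_change_given_no_hold)
    mix <- sum(ifelse(w > 0, w * p, 0))   # empty strata carry zero weight
    expect_equal(mix, p_marg, tolerance = 1e-12)
  }
})

test_that("silent-cycle groups partition the analysed cycles", {
  sim <- simulate_conversation(sim_config(duration_s = 300), seed = 21)
  res <- analyze_conversation(sim$traces, sim$intervals, sim$laughter,
                              default_config(fit_models = FALSE))
  g <- res$silent_groups
  expect_true(all(g$group %in% c("Silent", "Hold", "TT(S)")))
  expect_identical(anyDuplicated(paste(g$speaker, g$cycle)), 0L)
  # candidates are a subset of silent holds
  expect_true(all(res$candidates$during_silence))
  cand_key <- paste(res$candidates$speaker, res$candidates$cycle)
  expect_true(all(cand_key %in%
                    paste(res$holds$speaker, res$holds$cycle)))
  # every candidate cycle is grouped as Hold
  expect_true(all(cand_key %in% paste(g$speaker, g$cycle)[g$group == "Hold"]))
})
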