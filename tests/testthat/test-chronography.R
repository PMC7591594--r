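raw_iv <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(speaker = paste0("S", m[, 1]), t_start = m[, 2], t_end = m[, 3],
             stringsAsFactors = FALSE)
}

test_that("talkspurt merging follows the minimum-pause rule", {
  # gap 0.1 < 0.2 -> merged
  m <- merge_talkspurts(raw_iv(1, 0, 1.0, 1, 1.1, 2.0))
  expect_identical(nrow(m), 1L)
  expect_equal(c(m$t_start, m$t_end), c(0, 2.0))
  # gap 0.3 >= 0.2 -> kept apart
  m2 <- merge_talkspurts(raw_iv(1, 0, 1.0, 1, 1.3, 2.0))
  expect_identical(nrow(m2), 2L)
  # backchannel flag by the 1-s rule
  expect_true(merge_talkspurts(raw_iv(1, 0, 0.8))$is_backchannel)
  expect_false(merge_talkspurts(raw_iv(1, 0, 1.2))$is_backchannel)
  # overlapping same-speaker input is a format error
  expect_error(merge_talkspurts(raw_iv(1, 0, 1, 1, 0.5, 2)), "overlapping")
})

test_that("merging matches a sort-and-sweep oracle and is idempotent", {
  set.seed(10)
  for (k in 1:100) {
    n <- sample(3:12, 1)
    s <- sort(runif(n, 0, 30))
    e <- s + runif(n, 0.05, 1.5)
    # make input non-overlapping within the speaker
    for (i in seq_len(n - 1)) e[i] <- min(e[i], s[i + 1] - 0.01)
    keep <- e - s > 0.02
    s <- s[keep]; e <- e[keep]
    if (length(s) < 2) next
    d <- data.frame(speaker = "S1", t_start = s, t_end = e)
    m <- merge_talkspurts(d)
    o <- oracle_merge(s, e, 0.2)
    expect_equal(m$t_start, o$t_start, tolerance = 1e-12)
    expect_equal(m$t_end, o$t_end, tolerance = 1e-12)
    # idempotence
    m2 <- merge_talkspurts(m[, c("speaker", "t_start", "t_end")])
    expect_equal(m2$t_start, m$t_start)
    expect_equal(m2$t_end, m$t_end)
  }
})

test_that("basic chronogram categories match the textbook cases", {
  # A:[0,2], A:[3,5] -> WSS over [2,3]
  ev <- classify_intervals(merge_talkspurts(raw_iv(1, 0, 2, 1, 3, 5)))
  expect_identical(ev$base, "WSS")
  expect_equal(c(ev$t_start, ev$t_end), c(2, 3))
  # A:[0,2], B:[3,5] -> BSS over [2,3]
  ev <- classify_intervals(merge_talkspurts(raw_iv(1, 0, 2, 2, 3, 5)))
  expect_identical(ev$base, "BSS")
  expect_identical(ev$prev_speaker, "S1")
  expect_identical(ev$next_speaker, "S2")
  # A:[0,3], B:[2,5] -> BSO over [2,3]
  ev <- classify_intervals(merge_talkspurts(raw_iv(1, 0, 3, 2, 2, 5)))
  expect_identical(ev$base, "BSO")
  expect_equal(c(ev$t_start, ev$t_end), c(2, 3))
  # B fully inside A -> WSO, floor stays with A
  ev <- classify_intervals(merge_talkspurts(raw_iv(1, 0, 5, 2, 2, 3)))
  expect_identical(ev$base[1], "WSO")
  expect_identical(ev$prev_speaker[1], "S1")
  expect_identical(ev$next_speaker[1], "S1")
})

test_that("random three-party layouts match the grid-occupancy oracle", {
  set.seed(11)
  for (k in 1:100) {
    ts <- merge_talkspurts(random_layout())
    ev <- classify_intervals(ts)
    o <- oracle_chronogram(ts)
    if (is.null(o)) {
      expect_identical(nrow(ev), 0L)
      next
    }
    ev2 <- ev[order(ev$t_start, ev$t_end, ev$base), ]
    expect_identical(nrow(ev2), nrow(o))
    expect_identical(ev2$base, o$base)
    expect_identical(ev2$prev_speaker, o$prev_speaker)
    expect_identical(ev2$next_speaker, o$next_speaker)
    expect_equal(ev2$t_start, o$t_start, tolerance = 0.02)
  }
})

test_that("two-speaker non-overlapping input reduces to the classic chronogram", {
  set.seed(12)
  for (k in 1:20) {
    # alternating two-speaker talk with silences only
    t <- 0; rows <- list(); sp <- 1
    while (t < 30) {
      d <- runif(1, 0.5, 3)
      rows[[length(rows) + 1]] <- data.frame(speaker = paste0("S", sp),
                                             t_start = t, t_end = t + d)
      t <- t + d + runif(1, 0.25, 2)
      if (runif(1) < 0.5) sp <- 3 - sp
    }
    ts <- merge_talkspurts(do.call(rbind, rows))
    ev <- classify_intervals(ts)
    expect_true(all(ev$base %in% c("WSS", "BSS")))
    # every adjacent talkspurt pair yields exactly one event
    expect_identical(nrow(ev), nrow(ts) - 1L)
    expect_identical(ev$base == "WSS", ev$prev_speaker == ev$next_speaker)
  }
})

test_that("the inhalation augmentation follows the cycle landmarks", {
  ts <- merge_talkspurts(raw_iv(1, 0, 2, 2, 3, 5, 1, 6.5, 8))
  ev <- classify_intervals(ts)
  # exhalation continues into the next own talkspurt -> minus
  cyc_minus <- make_cycles(t_onset = -1, t_peak = 0, t_offset = 9,
                           v_onset = 0, v_peak = 1, v_offset = 0.2,
                           speaker = "S1")
  cyc_b <- make_cycles(t_onset = 2.2, t_peak = 2.8, t_offset = 6,
                       v_onset = 0, v_peak = 1, v_offset = 0,
                       speaker = "S2")
  ev1 <- augment_inh(ev, rbind(cyc_minus, cyc_b), ts)
  bss <- ev1[ev1$base == "BSS" & ev1$prev_speaker == "S1", ]
  expect_identical(bss$inh, "minus")
  # trough + inhalation before the next own talkspurt -> plus
  cyc_plus <- rbind(
    make_cycles(t_onset = -1, t_peak = 0, t_offset = 5.5,
                v_onset = 0, v_peak = 1, v_offset = 0, speaker = "S1"),
    make_cycles(t_onset = 5.5, t_peak = 6.2, t_offset = 9,
                v_onset = 0, v_peak = 1, v_offset = 0, speaker = "S1"))
  cyc_plus$cycle <- 1:2
  ev2 <- augment_inh(ev, rbind(cyc_plus, cyc_b), ts)
  bss2 <- ev2[ev2$base == "BSS" & ev2$prev_speaker == "S1", ]
  expect_identical(bss2$inh, "plus")
  expect_identical(bss2$inh_cycle, 2L)
  # a previous speaker who never speaks again -> n/a, excluded
  last <- ev2[ev2$prev_speaker == "S2", ]
  expect_true(all(last$inh == "na" | last$inh %in% c("plus", "minus")))
})

test_that("exclusion filters fire in the documented order", {
  ts <- merge_talkspurts(raw_iv(1, 0, 2, 2, 3, 5, 1, 6.5, 8))
  cyc <- rbind(
    make_cycles(c(-1, 5.5), c(0, 6.2), c(5.5, 9), 0, 1, 0, speaker = "S1"),
    make_cycles(2.2, 2.8, 6, 0, 1, 0, speaker = "S2"))
  cyc$cycle <- c(1:2, 1)
  ev <- augment_inh(classify_intervals(ts), cyc, ts)
  # clean events carry no exclusion
  ev0 <- apply_exclusions(ev, ts, cyc)
  expect_true(all(is.na(ev0$excluded) | ev0$excluded == "no_next_talkspurt"))
  # a bounding backchannel excludes the event
  ts_bc <- merge_talkspurts(raw_iv(1, 0, 2, 2, 3, 3.8, 1, 6.5, 8))
  cyc_bc <- rbind(
    make_cycles(c(-1, 5.5), c(0, 6.2), c(5.5, 9), 0, 1, 0, speaker = "S1"),
    make_cycles(2.2, 2.8, 6, 0, 1, 0, speaker = "S2"))
  cyc_bc$cycle <- c(1:2, 1)
  ev_bc <- apply_exclusions(augment_inh(classify_intervals(ts_bc), cyc_bc,
                                        ts_bc), ts_bc, cyc_bc)
  expect_true(all(ev_bc$excluded[ev_bc$next_ts ==
    ts_bc$ts[ts_bc$speaker == "S2"]] == "backchannel", na.rm = TRUE))
  # an edge inside an inhalation wins over the backchannel reason
  cyc_edge <- cyc_bc
  cyc_edge[cyc_edge$speaker == "S2", c("t_onset", "t_peak")] <- c(2.5, 3.2)
  ev_e <- apply_exclusions(augment_inh(classify_intervals(ts_bc), cyc_edge,
                                       ts_bc), ts_bc, cyc_edge)
  bss_e <- ev_e[ev_e$base == "BSS" & ev_e$next_speaker == "S2", ]
  expect_identical(bss_e$excluded, "edge_inhalation")
  # laughter overlap excludes
  la <- data.frame(speaker = "S1", t_start = 1.5, t_end = 2.2)
  ev_l <- apply_exclusions(augment_inh(classify_intervals(ts), cyc, ts),
                           flag_laughter(ts, la), cyc, la)
  expect_identical(ev_l$excluded[ev_l$base == "BSS" &
                                   ev_l$prev_speaker == "S1"], "laughter")
})

test_that("turn-taking events split into TT(S) and TT(O)", {
  # B starts 0.4 s after A stops -> TT(S); C starts while B speaks -> TT(O)
  ts <- merge_talkspurts(raw_iv(1, 0, 2, 2, 2.4, 5, 3, 4.2, 7))
  cyc <- rbind(
    make_cycles(-1, 0, 3, 0, 1, 0, speaker = "S1"),
    make_cycles(1.6, 2.2, 5.5, 0, 1, 0, speaker = "S2"),
    make_cycles(3.4, 4.0, 7.5, 0, 1, 0, speaker = "S3"))
  tt <- tt_events(ts, cyc)
  expect_identical(tt$kind[tt$speaker == "S2"], "TT(S)")
  expect_identical(tt$kind[tt$speaker == "S3"], "TT(O)")
  # talkspurt not preceded by an own inhalation produces no TT event
  cyc2 <- cyc[cyc$speaker != "S3", ]
  tt2 <- tt_events(ts, cyc2)
  expect_false("S3" %in% tt2$speaker)
})

test_that("counts are conserved across the inhalation augmentation", {
  sim <- simulate_conversation(sim_config(duration_s = 240), seed = 13)
  gt <- sim$ground_truth
  ev <- gt$events
  n_wss_bss_bso <- sum(ev$base %in% c("WSS", "BSS", "BSO"))
  n_lab <- sum(ev$inh %in% c("plus", "minus"))
  n_na <- sum(ev$inh == "na" & ev$base != "WSO")
  expect_identical(n_lab + n_na, n_wss_bss_bso)
  # categories are mutually exclusive and every event has exactly one base
  expect_true(all(table(ev$event) == 1))
})
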