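test_that("z-scoring standardises, is idempotent in effect, and matches a summation oracle", {
  tr <- rip_trace(c(0, 1, 2, 3, 4), 10, "a")
  z <- zscore_trace(tr)
  expect_equal(mean(z$samples), 0)
  expect_equal(sd(z$samples), 1)
  expect_identical(z$calibration, "zscored")

  set.seed(1)
  x <- rnorm(500)
  x <- (x - mean(x)) / sd(x)
  z2 <- zscore_trace(rip_trace(x, 100, "a"))
  expect_lt(max(abs(z2$samples - x)), 1e-9)

  set.seed(2)
  y <- cumsum(rnorm(300)) + sin(1:300 / 10)
  m <- oracle_moments(y)
  z3 <- zscore_trace(rip_trace(y, 100, "a"))
  expect_equal(z3$samples, (y - m[["mean"]]) / m[["sd"]], tolerance = 1e-12)

  expect_error(zscore_trace(rip_trace(rep(2, 10), 10, "a")), "degenerate")
})

test_that("sine-wave cycles land on the analytic extrema", {
  fs <- 100
  t <- seq(0, 30, by = 1 / fs)
  tr <- rip_trace(2 * sin(2 * pi * t / 4), fs, "a", "zscored")
  cyc <- segment_cycles(tr)
  expect_gt(nrow(cyc), 5)
  # troughs at 3, 7, 11, ...; peaks at 1, 5, 9, ...
  expect_true(all(abs(cyc$t_onset - (4 * (cyc$cycle - 1) + 3)) <= 1 / fs))
  expect_true(all(abs(cyc$t_peak - (4 * cyc$cycle + 1)) <= 1 / fs))
})

test_that("a superposed sub-threshold ripple does not change the cycle count", {
  fs <- 100
  t <- seq(0, 30, by = 1 / fs)
  base <- 2 * sin(2 * pi * t / 4)
  n0 <- nrow(segment_cycles(rip_trace(base, fs, "a", "zscored")))
  n1 <- nrow(segment_cycles(rip_trace(base + 0.3 * sin(2 * pi * t * 0.6),
                                      fs, "a", "zscored")))
  expect_identical(n0, n1)
})

test_that("a monotone ramp yields no cycles", {
  tr <- rip_trace(seq(0, 5, by = 0.01), 100, "a", "zscored")
  expect_identical(nrow(segment_cycles(tr)), 0L)
})

test_that("cycle landmarks strictly alternate and respect min_sep", {
  set.seed(42)
  for (k in 1:20) {
    tr <- random_zigzag()
    cyc <- segment_cycles(tr)
    if (nrow(cyc) == 0) next
    expect_true(all(cyc$v_peak > cyc$v_onset))
    expect_true(all(cyc$v_peak > cyc$v_offset))
    expect_true(all(cyc$v_peak - cyc$v_onset >= 1))
    expect_true(all(cyc$v_peak - cyc$v_offset >= 1))
    expect_true(all(cyc$t_onset < cyc$t_peak & cyc$t_peak < cyc$t_offset))
    if (nrow(cyc) > 1) {
      expect_true(all(cyc$t_onset[-1] >= cyc$t_offset[-nrow(cyc)] - 1e-9))
    }
  }
})

test_that("speaking volume matches the percentile definition", {
  # pooled landmark values {0, 1} in equal numbers -> span 1
  cyc <- make_cycles(t_onset = seq(0, by = 2, length.out = 10),
                     t_peak = seq(1, by = 2, length.out = 10),
                     t_offset = seq(1.5, by = 2, length.out = 10),
                     v_onset = 0, v_peak = 1, v_offset = 0)
  expect_equal(estimate_sv(cyc), 1)

  # pooled values 0..100 one each -> 90 under linear interpolation
  vals <- 0:100
  peaks <- vals + 1000
  cycx <- make_cycles(t_onset = seq(0, by = 3, length.out = 101),
                      t_peak = seq(1, by = 3, length.out = 101),
                      t_offset = seq(2, by = 3, length.out = 101),
                      v_onset = vals, v_peak = peaks, v_offset = vals)
  pooled <- c(vals, vals, peaks)  # every trough is a distinct landmark here
  expect_equal(estimate_sv(cycx),
               oracle_quantile(pooled, 0.95) - oracle_quantile(pooled, 0.05))
  # and on the plain 0..100 multiset the span is exactly 90
  expect_equal(oracle_quantile(0:100, 0.95) - oracle_quantile(0:100, 0.05), 90)

  # order independence
  set.seed(3)
  perm <- sample(nrow(cycx))
  expect_equal(estimate_sv(cycx[perm, ]), estimate_sv(cycx))

  expect_error(estimate_sv(make_cycles(0, 1, 2, 1, 1, 1)), "at least 2")
  cyc_flat <- make_cycles(c(0, 3), c(1, 4), c(2, 5), 1, 1, 1)
  expect_error(estimate_sv(cyc_flat), "degenerate")
})

test_that("REL is the windowed trough median, with a global fallback", {
  cyc <- make_cycles(t_onset = c(10, 14), t_peak = c(12, 16),
                     t_offset = c(14, 18),
                     v_onset = c(0.2, 0.9), v_peak = c(2, 2),
                     v_offset = c(0.9, 0.1))
  # window centred at 10 with width 4 only contains the trough at 10
  expect_equal(estimate_rel(cyc, 10, window_s = 4), 0.2)
  # all four troughs (0.2, 0.9 shared-dedup, 0.1): {0.2, 0.9, 0.1} -> 0.2
  expect_equal(estimate_rel(cyc, 14, window_s = 60), 0.2)
  expect_warning(rel <- estimate_rel(cyc, 500, window_s = 4), "falling back")
  expect_equal(rel, 0.2)
})

test_that("the dynamic REL track equals a brute-force windowed median", {
  set.seed(4)
  n <- 60
  t_on <- cumsum(runif(n, 2, 5))
  drift <- 0.5 * sin(t_on / 40)
  cyc <- make_cycles(t_onset = t_on, t_peak = t_on + 1, t_offset = t_on + 2,
                     v_onset = drift + rnorm(n, 0, 0.1),
                     v_peak = drift + 2,
                     v_offset = c((drift + rnorm(n, 0, 0.1))[-1], drift[n]))
  # contiguity: shared troughs
  cyc$t_offset <- c(cyc$t_onset[-1], cyc$t_onset[n] + 3)
  cyc$v_offset <- c(cyc$v_onset[-1], drift[n])
  rt <- rel_track(cyc, window_s = 60)
  tr_t <- c(cyc$t_onset, cyc$t_offset[n])
  tr_v <- c(cyc$v_onset, cyc$v_offset[n])
  for (i in seq_len(nrow(rt))) {
    expect_equal(rt$rel[i],
                 oracle_rel(tr_t, tr_v, rt$time[i], 60), tolerance = 1e-12)
  }
})

test_that("SV-unit conversion maps REL to 0 and REL + SV to 1, monotonically", {
  calib <- breath_calibration(sv = 0.8,
                              rel = data.frame(time = c(0, 100),
                                               rel = c(0.2, 0.4)))
  tr <- rip_trace(c(0.2, 1.0, 0.5, 0.2), 1 / 25, "a", "zscored")
  # times 0, 25, 50, 75 -> REL 0.2, 0.25, 0.3, 0.35
  out <- to_sv_units(tr, calib)
  expect_equal(out$samples[1], 0)
  expect_equal(out$samples[2], (1.0 - 0.25) / 0.8)
  expect_identical(out$calibration, "sv_units")
  # strict monotonicity in x at fixed t
  tr2 <- rip_trace(c(0.2, 0.4), 1, "a", "zscored")
  tr3 <- rip_trace(c(0.3, 0.5), 1, "a", "zscored")
  expect_true(all(to_sv_units(tr3, calib)$samples >
                    to_sv_units(tr2, calib)$samples))
})

test_that("resampling preserves a linear signal and retimes correctly", {
  tr <- rip_trace(seq(0, 1, length.out = 51), 50, "a")
  r <- resample_trace(tr, 100)
  expect_equal(r$sample_rate, 100)
  expect_equal(r$samples, seq(0, 1, length.out = 101), tolerance = 1e-12)
})
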