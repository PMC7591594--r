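#' Breath-hold (plateau) detection
#'
#' A respiratory hold shows up as a plateau in the RIP signal. Detection
#' works per breathing cycle: a histogram of the cycle's signal values is
#' scanned for a prominent mode, and holds are the maximal stretches of
#' time during which the signal stays within a margin around the mode
#' level. Runs separated by less than the minimum gap are merged; runs
#' shorter than the minimum hold duration are dropped. Holds are assigned
#' to the exhalation when at least half of their duration falls after the
#' cycle peak; inhalation-side plateaus are discarded.
#'
#' @param trace a [rip_trace()] in SV units.
#' @param cycles cycle table (same units as `trace`).
#' @param min_hold_s minimum hold duration in seconds (default 0.25).
#' @param min_gap_s minimum gap between two holds in seconds (default 0.15);
#'   runs separated by less are merged.
#' @param margin_frac margin around the mode level, as a fraction of the
#'   cycle's exhalation amplitude `v_peak - v_offset` (default 0.025).
#' @param n_bins number of equal-width histogram bins across the cycle's
#'   value range (default 100).
#' @param prominence_ratio a mode is prominent when its bin count is at
#'   least this multiple of the median bin count (default 3).
#' @param smooth_ms length of the moving-average window applied to the
#'   cycle's samples before histogramming and run detection (default 100
#'   ms). This suppresses sensor noise that would otherwise fragment
#'   plateau runs and flatten the histogram mode; set to 0 to disable.
#' @param landmark_margin_s runs overlapping this neighbourhood of the
#'   cycle peak or offset trough are discarded (default 0.25 s): around
#'   the turning points the rounded extremum itself dwells inside the
#'   margin band and is indistinguishable from a brief plateau.
#' @return data.frame with one row per hold: `speaker`, `cycle`, `t_start`,
#'   `t_end`, `level` (mode level, trace units) and `during_silence`
#'   (logical, `NA` until [filter_silent_holds()] is applied).
#' @export
detect_holds <- function(trace, cycles, min_hold_s = 0.25, min_gap_s = 0.15,
                         margin_frac = 0.025, n_bins = 100,
                         prominence_ratio = 3, smooth_ms = 100,
                         landmark_margin_s = 0.25) {
  stopifnot(inherits(trace, "rip_trace"))
  empty <- data.frame(speaker = character(), cycle = integer(),
                      t_start = numeric(), t_end = numeric(),
                      level = numeric(), during_silence = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(cycles) == 0L) return(empty)
  tt <- trace_times(trace)
  x_all <- trace$samples
  if (smooth_ms > 0) {
    w <- max(1L, round(smooth_ms / 1000 * trace$sample_rate))
    x_all <- moving_average(x_all, w)
  }
  out <- vector("list", nrow(cycles))
  for (i in seq_len(nrow(cycles))) {
    cy <- cycles[i, ]
    if (cy$t_offset - cy$t_onset < min_hold_s) next
    sel <- which(tt >= cy$t_onset & tt < cy$t_offset)
    if (length(sel) < 3L) next
    x <- x_all[sel]
    rng <- range(x)
    if (diff(rng) <= 0) next
    counts <- tabulate(
      pmin(n_bins, pmax(1L, 1L + floor((x - rng[1]) / diff(rng) * n_bins))),
      nbins = n_bins)
    mode_bin <- which.max(counts)
    if (counts[mode_bin] < prominence_ratio * max(stats::median(counts), 1)) {
      next
    }
    level <- rng[1] + (mode_bin - 0.5) / n_bins * diff(rng)
    margin <- margin_frac * (cy$v_peak - cy$v_offset)
    runs <- band_runs(tt[sel], abs(x - level) <= margin,
                      min_gap_s = min_gap_s, min_len_s = min_hold_s)
    if (nrow(runs) == 0L) next
    # assign to the exhalation: >= 50% of duration after the peak
    after <- (pmin(runs$t_end, cy$t_offset) - pmax(runs$t_start, cy$t_peak))
    keep <- after >= 0.5 * (runs$t_end - runs$t_start)
    runs <- runs[keep, , drop = FALSE]
    if (nrow(runs) == 0L) next
    # trim away the neighbourhood of the turning points, where the
    # rounded extremum dwells inside the margin band (corner, not plateau)
    eps <- landmark_margin_s
    runs$t_start <- pmax(runs$t_start, cy$t_peak + eps)
    runs$t_end <- pmin(runs$t_end, cy$t_offset - eps)
    runs <- runs[runs$t_end - runs$t_start >= min_hold_s, , drop = FALSE]
    if (nrow(runs) == 0L) next
    out[[i]] <- data.frame(speaker = cy$speaker, cycle = cy$cycle,
                           t_start = runs$t_start, t_end = runs$t_end,
                           level = level, during_silence = NA,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

# centred moving average with edge replication
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  half <- w %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  k <- 2L * half + 1L
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(half + 1L):(half + length(x))]
}

# Maximal TRUE runs over sample times; gaps < min_gap_s merged, runs
# shorter than min_len_s dropped (after merging).
band_runs <- function(t, inside, min_gap_s, min_len_s) {
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(t_start = t[starts[r$values]], t_end = t[ends[r$values]])
  if (nrow(runs) == 0L) return(runs)
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (j in 2:nrow(runs)) {
      if (runs$t_start[j] - merged$t_end[nrow(merged)] < min_gap_s) {
        merged$t_end[nrow(merged)] <- runs$t_end[j]
      } else {
        merged <- rbind(merged, runs[j, ])
      }
    }
  }
  merged[merged$t_end - merged$t_start >= min_len_s, , drop = FALSE]
}

#' Keep only holds produced during silent exhalations
#'
#' Speech itself produces slowly decaying quasi-plateaus that the histogram
#' method mistakes for holds, so only hold candidates whose span does not
#' overlap any of the speaker's own talkspurts are retained.
#'
#' @param holds hold table from [detect_holds()].
#' @param talkspurts talkspurt table; only rows matching each hold's
#'   speaker are considered.
#' @return the retained holds with `during_silence = TRUE`.
#' @export
filter_silent_holds <- function(holds, talkspurts) {
  if (nrow(holds) == 0L) return(holds)
  keep <- vapply(seq_len(nrow(holds)), function(i) {
    own <- talkspurts[talkspurts$speaker == holds$speaker[i], , drop = FALSE]
    !any(own$t_start < holds$t_end[i] & own$t_end > holds$t_start[i])
  }, logical(1))
  out <- holds[keep, , drop = FALSE]
  if (nrow(out) > 0L) out$during_silence <- TRUE
  out
}
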