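#' Breathing-cycle segmentation and calibration
#'
#' Segmentation locates peaks and troughs in the z-scored respiratory signal
#' separated by at least `min_sep` standard deviations and assembles them
#' into breathing cycles (trough, peak, trough). The speaker's speaking
#' volume (SV) is the span between the 5th and 95th percentiles of all
#' landmark values; the resting expiratory level (REL) is the median trough
#' value within a sliding window (60 s by default).
#'
#' @name segmentation
NULL

# All strict local extrema of x, with flat runs collapsed to their first
# sample (tie rule). Returns data.frame(idx, value, type).
find_local_extrema <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) {
    return(data.frame(idx = integer(), value = numeric(),
                      type = character(), stringsAsFactors = FALSE))
  }
  run_start <- cumsum(c(1L, r$lengths[-k]))
  v <- r$values
  mid <- 2:(k - 1L)
  is_max <- v[mid] > v[mid - 1L] & v[mid] > v[mid + 1L]
  is_min <- v[mid] < v[mid - 1L] & v[mid] < v[mid + 1L]
  keep <- is_max | is_min
  data.frame(
    idx = run_start[mid][keep],
    value = v[mid][keep],
    type = ifelse(is_max[keep], "max", "min"),
    stringsAsFactors = FALSE
  )
}

# Greedy landmark scan over the extrema sequence (O(n)): keeps the most
# extreme landmark of each phase and emits a reversal only once the signal
# has moved by at least min_sep, so the retained landmarks strictly
# alternate and every adjacent peak/trough pair differs by >= min_sep.
scan_landmarks <- function(ext, min_sep) {
  n <- nrow(ext)
  keep_idx <- integer()
  if (n == 0L) return(ext[keep_idx, , drop = FALSE])
  v <- ext$value
  dir <- 0L
  lo <- hi <- 1L            # candidate trough / peak positions
  for (i in seq_len(n)) {
    if (dir == 0L) {
      if (v[i] < v[lo]) lo <- i
      if (v[i] > v[hi]) hi <- i
      if (v[hi] - v[lo] >= min_sep) {
        if (lo < hi) { keep_idx <- c(keep_idx, lo); dir <- 1L }
        else { keep_idx <- c(keep_idx, hi); dir <- -1L }
      }
    } else if (dir == 1L) {  # rising: tracking the candidate peak
      if (v[i] > v[hi]) hi <- i
      if (v[hi] - v[i] >= min_sep) {
        keep_idx <- c(keep_idx, hi)
        dir <- -1L
        lo <- i
      }
    } else {                 # falling: tracking the candidate trough
      if (v[i] < v[lo]) lo <- i
      if (v[i] - v[lo] >= min_sep) {
        keep_idx <- c(keep_idx, lo)
        dir <- 1L
        hi <- i
      }
    }
  }
  # close the final phase if it has moved far enough
  if (dir == 1L && length(keep_idx) &&
      v[hi] - v[keep_idx[length(keep_idx)]] >= min_sep) {
    keep_idx <- c(keep_idx, hi)
  } else if (dir == -1L && length(keep_idx) &&
             v[keep_idx[length(keep_idx)]] - v[lo] >= min_sep) {
    keep_idx <- c(keep_idx, lo)
  }
  ext[keep_idx, , drop = FALSE]
}

# retype a strictly alternating landmark sequence from its values
retype_alternating <- function(ext) {
  n <- nrow(ext)
  if (n >= 2L) {
    first_min <- ext$value[1L] < ext$value[2L]
    ext$type <- rep(if (first_min) c("min", "max") else c("max", "min"),
                    length.out = n)
  }
  ext
}

#' Segment a z-scored trace into breathing cycles
#'
#' Finds all strict local extrema (the first sample of a flat extremum is
#' taken as the landmark), greedily prunes alternation violations keeping
#' the more extreme landmark, and removes adjacent peak/trough pairs whose
#' values differ by less than `min_sep`, smallest difference first. Cycles
#' are then assembled as trough-peak-trough triples.
#'
#' @param trace a z-scored [rip_trace()] (or one already in SV units).
#' @param min_sep minimum peak-trough separation in the units of the trace
#'   (default 1.0, i.e. one standard deviation on a z-scored trace).
#' @return data.frame with one row per cycle: `speaker`, `cycle`,
#'   `t_onset`, `t_peak`, `t_offset` (inhalation-onset trough, peak,
#'   exhalation-offset trough, seconds), `v_onset`, `v_peak`, `v_offset`
#'   (signal values) and `silent` (logical, `NA` until speech activity is
#'   known; see [mark_silent_cycles()]).
#' @export
segment_cycles <- function(trace, min_sep = 1.0) {
  stopifnot(inherits(trace, "rip_trace"))
  if (trace$calibration == "raw") {
    stop("segment_cycles() expects a z-scored trace; call zscore_trace() first",
         call. = FALSE)
  }
  ext <- retype_alternating(
    scan_landmarks(find_local_extrema(trace$samples), min_sep))
  empty <- data.frame(
    speaker = character(), cycle = integer(),
    t_onset = numeric(), t_peak = numeric(), t_offset = numeric(),
    v_onset = numeric(), v_peak = numeric(), v_offset = numeric(),
    silent = logical(), stringsAsFactors = FALSE)
  if (nrow(ext) < 3L) return(empty)
  # first landmark must be a trough
  if (ext$type[1L] != "min") ext <- ext[-1L, , drop = FALSE]
  n_cyc <- (nrow(ext) - 1L) %/% 2L
  if (n_cyc < 1L) return(empty)
  tt <- trace_times(trace)
  i_on <- seq(1L, by = 2L, length.out = n_cyc)
  data.frame(
    speaker = trace$speaker_id,
    cycle = seq_len(n_cyc),
    t_onset = tt[ext$idx[i_on]],
    t_peak = tt[ext$idx[i_on + 1L]],
    t_offset = tt[ext$idx[i_on + 2L]],
    v_onset = ext$value[i_on],
    v_peak = ext$value[i_on + 1L],
    v_offset = ext$value[i_on + 2L],
    silent = NA,
    stringsAsFactors = FALSE
  )
}

# Pool landmark values of a cycle table: all peaks plus all troughs, with
# troughs shared by consecutive cycles counted once (deduplicated on time).
pool_landmarks <- function(cycles) {
  troughs <- rbind(
    data.frame(t = cycles$t_onset, v = cycles$v_onset),
    data.frame(t = cycles$t_offset, v = cycles$v_offset))
  troughs <- troughs[!duplicated(troughs$t), , drop = FALSE]
  list(peaks = data.frame(t = cycles$t_peak, v = cycles$v_peak),
       troughs = troughs[order(troughs$t), , drop = FALSE])
}

#' Refine landmark times by a two-segment corner fit
#'
#' Sensor noise jitters the raw argmin/argmax of shallow extrema by more
#' than the corner geometry warrants. Around each first-pass landmark a
#' corner model -- two straight lines meeting at the landmark -- is
#' fitted by least squares for every candidate split point in a window
#' (capped at the midpoints to the neighbouring landmarks), and the
#' landmark is moved to the split with the smallest residual sum of
#' squares. Under white sensor noise this is the maximum-likelihood
#' corner location and, unlike further smoothing, it does not displace
#' corners with asymmetric slopes.
#'
#' @param cycles cycle table from [segment_cycles()] (one speaker,
#'   contiguous cycles).
#' @param trace the z-scored trace the cycles were found on.
#' @param win_s refinement half-window in seconds (default 0.40).
#' @param value_smooth_s window of the moving average used to re-read the
#'   landmark value at the refined time (default 0.10 s).
#' @return the cycle table with refined landmark times and values.
#' @export
refine_landmarks <- function(cycles, trace, win_s = 0.40,
                             value_smooth_s = 0.10) {
  if (nrow(cycles) == 0L) return(cycles)
  fs <- trace$sample_rate
  tt <- trace_times(trace)
  y <- trace$samples
  ys <- moving_average(y, max(1L, round(value_smooth_s * fs)))
  lm_t <- c(rbind(cycles$t_onset, cycles$t_peak),
            cycles$t_offset[nrow(cycles)])
  n <- length(lm_t)
  out_t <- lm_t
  for (i in seq_len(n)) {
    lo <- lm_t[i] - win_s
    hi <- lm_t[i] + win_s
    if (i > 1L) lo <- max(lo, (lm_t[i - 1L] + lm_t[i]) / 2)
    if (i < n) hi <- min(hi, (lm_t[i] + lm_t[i + 1L]) / 2)
    sel <- which(tt >= lo & tt <= hi)
    if (length(sel) < 7L) next
    out_t[i] <- tt[sel[corner_split(tt[sel], y[sel])]]
  }
  i_on <- seq(1L, by = 2L, length.out = nrow(cycles))
  val <- function(t0) ys[pmin(length(ys), pmax(1L, round((t0 - tt[1]) * fs) + 1L))]
  cycles$t_onset <- out_t[i_on]
  cycles$t_peak <- out_t[i_on + 1L]
  cycles$t_offset <- out_t[i_on + 2L]
  cycles$v_onset <- val(cycles$t_onset)
  cycles$v_peak <- val(cycles$t_peak)
  cycles$v_offset <- val(cycles$t_offset)
  cycles
}

# index (into x) of the best two-segment split by least squares; prefix
# sums give the residual of a straight-line fit to every prefix/suffix
corner_split <- function(x, y) {
  n <- length(x)
  cx <- cumsum(x); cx2 <- cumsum(x^2)
  cy <- cumsum(y); cy2 <- cumsum(y^2); cxy <- cumsum(x * y)
  sse_prefix <- function(k) {
    sxx <- cx2[k] - cx[k]^2 / k
    sxy <- cxy[k] - cx[k] * cy[k] / k
    syy <- cy2[k] - cy[k]^2 / k
    ifelse(sxx > 1e-12, syy - sxy^2 / sxx, syy)
  }
  ks <- 3:(n - 3)
  left <- sse_prefix(ks)
  tx <- cx[n]; tx2 <- cx2[n]; ty <- cy[n]; ty2 <- cy2[n]; txy <- cxy[n]
  m <- n - ks
  sxx <- (tx2 - cx2[ks]) - (tx - cx[ks])^2 / m
  sxy <- (txy - cxy[ks]) - (tx - cx[ks]) * (ty - cy[ks]) / m
  syy <- (ty2 - cy2[ks]) - (ty - cy[ks])^2 / m
  right <- ifelse(sxx > 1e-12, syy - sxy^2 / sxx, syy)
  ks[which.min(left + right)]
}

#' Speaking volume (SV) of a speaker
#'
#' The interval between the 5th and 95th percentiles of all peak and trough
#' values of the segmented cycles. Troughs shared by consecutive cycles are
#' counted once. Percentiles use linear interpolation between order
#' statistics (`stats::quantile()` type 7) by default.
#'
#' @param cycles cycle table from [segment_cycles()] (>= 2 cycles).
#' @param probs the two probabilities defining the span (default 0.05, 0.95).
#' @param type quantile type passed to [stats::quantile()].
#' @return the SV span (single positive number, signal units).
#' @export
estimate_sv <- function(cycles, probs = c(0.05, 0.95), type = 7) {
  if (nrow(cycles) < 2L) {
    stop("estimate_sv() needs at least 2 cycles", call. = FALSE)
  }
  lm <- pool_landmarks(cycles)
  vals <- c(lm$peaks$v, lm$troughs$v)
  q <- stats::quantile(vals, probs = probs, type = type, names = FALSE)
  sv <- diff(q)
  if (sv <= 0) {
    stop("degenerate calibration: pooled landmark values have zero span",
         call. = FALSE)
  }
  sv
}

#' Resting expiratory level (REL) at a time point
#'
#' Median trough value within a window around `t`. If no trough falls in
#' the window, the global trough median is returned with a warning.
#'
#' @param cycles cycle table from [segment_cycles()].
#' @param t time in seconds at which REL is evaluated.
#' @param window_s window length in seconds (default 60).
#' @param align `"centred"` (window `[t - w/2, t + w/2]`) or `"trailing"`
#'   (`[t - w, t]`).
#' @return REL value (signal units).
#' @export
estimate_rel <- function(cycles, t, window_s = 60,
                         align = c("centred", "trailing")) {
  align <- match.arg(align)
  tr <- pool_landmarks(cycles)$troughs
  lo <- if (align == "centred") t - window_s / 2 else t - window_s
  hi <- if (align == "centred") t + window_s / 2 else t
  sel <- tr$t >= lo & tr$t <= hi
  if (!any(sel)) {
    warning("no troughs in REL window; falling back to global trough median")
    return(stats::median(tr$v))
  }
  stats::median(tr$v[sel])
}

#' Dynamic REL track
#'
#' Evaluates [estimate_rel()] at every trough time, giving the per-trough
#' (time, REL) series used for dynamic baseline correction.
#'
#' @inheritParams estimate_rel
#' @return data.frame with columns `time` and `rel`, times strictly
#'   increasing.
#' @export
rel_track <- function(cycles, window_s = 60, align = c("centred", "trailing")) {
  align <- match.arg(align)
  tr <- pool_landmarks(cycles)$troughs
  data.frame(
    time = tr$t,
    rel = vapply(tr$t, function(t0) {
      estimate_rel(cycles, t0, window_s = window_s, align = align)
    }, numeric(1))
  )
}

#' Speaker calibration (SV span and dynamic REL)
#'
#' @param sv speaking-volume span (> 0, signal units).
#' @param rel a data.frame as returned by [rel_track()].
#' @param window_s REL window used to build the track.
#' @return an object of class `breath_calibration`.
#' @export
breath_calibration <- function(sv, rel, window_s = 60) {
  stopifnot(is.numeric(sv), length(sv) == 1L, sv > 0)
  stopifnot(is.data.frame(rel), all(c("time", "rel") %in% names(rel)))
  if (is.unsorted(rel$time, strictly = TRUE)) {
    stop("rel track times must be strictly increasing", call. = FALSE)
  }
  structure(list(sv = sv, rel = rel, window_s = window_s),
            class = "breath_calibration")
}

#' @export
print.breath_calibration <- function(x, ...) {
  cat(sprintf("<breath_calibration> sv = %.4g, REL track of %d troughs (%g-s window)\n",
              x$sv, nrow(x$rel), x$window_s))
  invisible(x)
}

#' Calibrate a speaker from their segmented cycles
#'
#' Convenience wrapper building a [breath_calibration()] from a cycle table:
#' SV from the pooled landmark percentiles and REL from the windowed trough
#' median.
#'
#' @inheritParams estimate_rel
#' @inheritParams estimate_sv
#' @return a `breath_calibration`.
#' @export
calibrate_speaker <- function(cycles, window_s = 60,
                              align = c("centred", "trailing"),
                              probs = c(0.05, 0.95), type = 7) {
  align <- match.arg(align)
  breath_calibration(
    sv = estimate_sv(cycles, probs = probs, type = type),
    rel = rel_track(cycles, window_s = window_s, align = align),
    window_s = window_s
  )
}

# REL evaluated at arbitrary times by linear interpolation between trough
# REL values (constant beyond the first/last trough).
rel_at <- function(calib, t) {
  if (nrow(calib$rel) == 1L) {
    return(rep(calib$rel$rel, length(t)))
  }
  stats::approx(calib$rel$time, calib$rel$rel, xout = t, rule = 2)$y
}

#' Express a trace in speaking-volume units
#'
#' Maps each sample `x` at time `t` to `(x - REL(t)) / sv`: the dynamic
#' resting expiratory level maps to 0 and a value one full speaking volume
#' above REL maps to 1.
#'
#' @param trace a z-scored [rip_trace()].
#' @param calib a [breath_calibration()] in the same units as `trace`.
#' @return the trace in SV units (`calibration = "sv_units"`).
#' @export
to_sv_units <- function(trace, calib) {
  stopifnot(inherits(trace, "rip_trace"), inherits(calib, "breath_calibration"))
  out <- trace
  out$samples <- (trace$samples - rel_at(calib, trace_times(trace))) / calib$sv
  out$calibration <- "sv_units"
  out
}

#' Express cycle landmark values in speaking-volume units
#'
#' Applies the same affine map as [to_sv_units()] to the landmark values of
#' a cycle table, using the dynamic REL at each landmark's own time.
#'
#' @param cycles cycle table from [segment_cycles()].
#' @param calib a [breath_calibration()].
#' @return the cycle table with `v_onset`, `v_peak`, `v_offset` in SV units.
#' @export
calibrate_cycles <- function(cycles, calib) {
  out <- cycles
  out$v_onset <- (cycles$v_onset - rel_at(calib, cycles$t_onset)) / calib$sv
  out$v_peak <- (cycles$v_peak - rel_at(calib, cycles$t_peak)) / calib$sv
  out$v_offset <- (cycles$v_offset - rel_at(calib, cycles$t_offset)) / calib$sv
  out
}

#' Flag cycles that do not overlap the speaker's own speech
#'
#' @param cycles cycle table for one speaker.
#' @param talkspurts talkspurt table (see [merge_talkspurts()]); only rows
#'   of the cycle's own speaker are considered.
#' @return the cycle table with the `silent` column filled in.
#' @export
mark_silent_cycles <- function(cycles, talkspurts) {
  if (nrow(cycles) == 0L) return(cycles)
  own <- talkspurts[talkspurts$speaker == cycles$speaker[1L], , drop = FALSE]
  cycles$silent <- vapply(seq_len(nrow(cycles)), function(i) {
    !any(own$t_start < cycles$t_offset[i] & own$t_end > cycles$t_onset[i])
  }, logical(1))
  cycles
}
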