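#' Kinematic breathing features of interactional intervals
#'
#' For every non-WSO turn event the exhalation following the previous
#' speaker's talkspurt (for WSS, the exhalation following the pre-pausal
#' talkspurt) yields: amplitude in speaking-volume (SV) units, duration in
#' log2 seconds, slope in SV per second (negative: falling lung volume),
#' and lung-volume levels (fractions of SV relative to the dynamic REL) at
#' the exhalation onset and offset, plus a flag for a co-occurring
#' respiratory hold. For `+INH` events and turn-initial (TT) talkspurts
#' the linked inhalation yields duration (log2 s), amplitude (SV), slope
#' (SV/s, positive) and offset level, plus the speech lag (log2 s between
#' inhalation onset and speech onset) where defined (WSS+INH, TT(S),
#' TT(O)).
#'
#' @name feature_extraction
NULL

# exhalation duration floored at one sample period before log2
log2_dur <- function(d, floor_s) log2(pmax(d, floor_s))

#' Exhalatory features of turn events
#'
#' @param events event table from [apply_exclusions()] (must carry
#'   `anchor_cycle`).
#' @param cycles cycle table in SV units (see [calibrate_cycles()]).
#' @param holds silent-exhalation hold table (see
#'   [filter_silent_holds()]), used for the `hold_present` flag.
#' @param floor_s duration floor in seconds before taking log2 (default
#'   0.01, one sample at the 100 Hz working rate).
#' @return the event table with columns `exh_amplitude`,
#'   `exh_duration_log2s`, `exh_slope`, `exh_onset_level`,
#'   `exh_offset_level`, `hold_present` appended (NA where no anchoring
#'   exhalation exists).
#' @export
exhalation_features <- function(events, cycles, holds, floor_s = 0.01) {
  n <- nrow(events)
  amp <- dur <- slope <- onset <- offset <- rep(NA_real_, n)
  hold <- rep(NA, n)
  for (i in seq_len(n)) {
    if (events$base[i] == "WSO" || is.na(events$anchor_cycle[i])) next
    cy <- cycles[cycles$speaker == events$prev_speaker[i] &
                   cycles$cycle == events$anchor_cycle[i], ]
    if (nrow(cy) != 1L) next
    d <- cy$t_offset - cy$t_peak
    if (d <= 0) stop("data error: non-positive exhalation duration", call. = FALSE)
    amp[i] <- cy$v_peak - cy$v_offset
    dur[i] <- log2_dur(d, floor_s)
    slope[i] <- -amp[i] / d
    onset[i] <- cy$v_peak
    offset[i] <- cy$v_offset
    h <- holds[holds$speaker == cy$speaker, , drop = FALSE]
    hold[i] <- any(h$t_start < cy$t_offset & h$t_end > cy$t_peak)
  }
  events$exh_amplitude <- amp
  events$exh_duration_log2s <- dur
  events$exh_slope <- slope
  events$exh_onset_level <- onset
  events$exh_offset_level <- offset
  events$hold_present <- hold
  events
}

#' Inhalatory features of +INH events and TT events
#'
#' For a turn event the linked inhalation is the one preceding the
#' previous speaker's next talkspurt (`inh_cycle` from [augment_inh()]);
#' for a TT event it is the inhalation preceding the incoming talkspurt.
#' The inhalatory slope is amplitude over inhalation duration by default;
#' `slope_denominator = "speech_lag"` divides by the speech lag instead,
#' where it is defined.
#'
#' @param x an event table (from [augment_inh()]) or a TT table (from
#'   [tt_events()]).
#' @param cycles cycle table in SV units.
#' @param talkspurts talkspurt table.
#' @param slope_denominator `"duration"` or `"speech_lag"`.
#' @param floor_s duration floor before log2.
#' @return `x` with columns `inh_duration_log2s`, `inh_amplitude`,
#'   `inh_slope`, `inh_offset_level`, `speech_lag_log2s` appended.
#' @export
inhalation_features <- function(x, cycles, talkspurts,
                                slope_denominator = c("duration", "speech_lag"),
                                floor_s = 0.01) {
  slope_denominator <- match.arg(slope_denominator)
  n <- nrow(x)
  dur <- amp <- slope <- offset <- lag <- rep(NA_real_, n)
  is_tt <- !is.null(x$kind)
  for (i in seq_len(n)) {
    if (is_tt) {
      sp <- x$speaker[i]
      ci <- x$inh_cycle[i]
      speech_on <- x$t_start[i]
      lag_defined <- TRUE
    } else {
      if (!identical(x$inh[i], "plus")) next
      sp <- x$prev_speaker[i]
      ci <- x$inh_cycle[i]
      speech_on <- x$next_own_onset[i]
      lag_defined <- x$base[i] == "WSS"
    }
    if (is.na(ci)) next
    cy <- cycles[cycles$speaker == sp & cycles$cycle == ci, ]
    if (nrow(cy) != 1L) next
    d <- cy$t_peak - cy$t_onset
    dur[i] <- log2_dur(d, floor_s)
    amp[i] <- cy$v_peak - cy$v_onset
    offset[i] <- cy$v_peak
    if (lag_defined) {
      l <- speech_on - cy$t_onset
      if (l <= 0) stop("data error: speech onset precedes inhalation onset",
                       call. = FALSE)
      lag[i] <- log2_dur(l, floor_s)
    }
    slope[i] <- switch(slope_denominator,
                       duration = amp[i] / d,
                       speech_lag = if (lag_defined) amp[i] / (speech_on - cy$t_onset) else NA_real_)
  }
  x$inh_duration_log2s <- dur
  x$inh_amplitude <- amp
  x$inh_slope <- slope
  x$inh_offset_level <- offset
  x$speech_lag_log2s <- lag
  x
}

#' Build the combined feature table for statistical modelling
#'
#' One wide row per turn event (exhalatory features, plus inhalatory
#' features for `+INH` events) and per TT event (inhalatory features
#' only), with the augmented category label.
#'
#' @param events event table after [apply_exclusions()].
#' @param tt TT event table from [tt_events()].
#' @param cycles cycle table in SV units.
#' @param talkspurts talkspurt table.
#' @param holds silent-hold table.
#' @param slope_denominator passed to [inhalation_features()].
#' @param floor_s duration floor before log2.
#' @return data.frame with columns `id`, `category`, `speaker`, the
#'   exhalatory and inhalatory feature columns, and `excluded`.
#' @export
feature_table <- function(events, tt, cycles, talkspurts, holds,
                          slope_denominator = "duration", floor_s = 0.01) {
  ev <- events[events$base != "WSO", , drop = FALSE]
  ev <- exhalation_features(ev, cycles, holds, floor_s = floor_s)
  ev <- inhalation_features(ev, cycles, talkspurts,
                            slope_denominator = slope_denominator,
                            floor_s = floor_s)
  feat_cols <- c("exh_amplitude", "exh_duration_log2s", "exh_slope",
                 "exh_onset_level", "exh_offset_level", "hold_present",
                 "inh_duration_log2s", "inh_amplitude", "inh_slope",
                 "inh_offset_level", "speech_lag_log2s")
  ev_rows <- data.frame(id = paste0("ev", ev$event),
                        category = event_category(ev),
                        speaker = ev$prev_speaker,
                        ev[, feat_cols, drop = FALSE],
                        excluded = ev$excluded, stringsAsFactors = FALSE)
  tt2 <- inhalation_features(tt, cycles, talkspurts,
                             slope_denominator = slope_denominator,
                             floor_s = floor_s)
  if (nrow(tt2) > 0L) {
    tt_rows <- data.frame(id = paste0("tt", tt2$ts),
                          category = tt2$kind,
                          speaker = tt2$speaker,
                          exh_amplitude = NA_real_,
                          exh_duration_log2s = NA_real_,
                          exh_slope = NA_real_,
                          exh_onset_level = NA_real_,
                          exh_offset_level = NA_real_,
                          hold_present = NA,
                          tt2[, c("inh_duration_log2s", "inh_amplitude",
                                  "inh_slope", "inh_offset_level",
                                  "speech_lag_log2s")],
                          excluded = tt2$excluded, stringsAsFactors = FALSE)
    ev_rows <- rbind(ev_rows, tt_rows)
  }
  rownames(ev_rows) <- NULL
  ev_rows
}

#' Flag rows with extreme slope values
#'
#' Rows whose exhalatory or inhalatory slope lies at least `k` standard
#' deviations from the mean are marked `excluded = "extreme_slope"`. The
#' mean and SD are computed separately for the two slope types over all
#' currently non-excluded rows of the whole conversation set. With zero
#' SD nothing is excluded. When `recompute = FALSE`, previously stored
#' statistics (attribute `slope_stats`) are reused, making the operation
#' idempotent on an already filtered table.
#'
#' @param features feature table from [feature_table()].
#' @param k number of standard deviations (default 3).
#' @param recompute recompute the slope statistics (default TRUE).
#' @return the feature table with extreme rows flagged; the statistics
#'   used are stored in the `slope_stats` attribute.
#' @export
flag_extreme_slopes <- function(features, k = 3, recompute = TRUE) {
  stats_of <- function(v) {
    v <- v[is.finite(v)]
    c(mean = mean(v), sd = if (length(v) >= 2L) stats::sd(v) else 0)
  }
  if (recompute || is.null(attr(features, "slope_stats"))) {
    ok <- is.na(features$excluded)
    st <- list(exh = stats_of(features$exh_slope[ok]),
               inh = stats_of(features$inh_slope[ok]))
  } else {
    st <- attr(features, "slope_stats")
  }
  extreme <- function(v, s) {
    !is.na(v) & s[["sd"]] > 0 & abs(v - s[["mean"]]) >= k * s[["sd"]]
  }
  hit <- extreme(features$exh_slope, st$exh) | extreme(features$inh_slope, st$inh)
  features$excluded[is.na(features$excluded) & hit] <- "extreme_slope"
  attr(features, "slope_stats") <- st
  features
}
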