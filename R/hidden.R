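#' Hidden turn-taking events
#'
#' Silence-based chronograms hide some interactional intentions. Two are
#' recoverable from breathing: pause interruptions (silences during which
#' the previous speaker keeps holding their breath) are captured by the
#' conditional probability of speaker change given a respiratory hold, and
#' abandoned turn initiations are captured by holds at the very top of a
#' silent exhalation -- a participant inhales, holds their breath as if
#' about to speak, then exhales without speaking.
#'
#' @name hidden_events
NULL

#' Relative position of holds within their exhalation
#'
#' @param holds hold table (rows matched to `cycles` by `speaker` and
#'   `cycle`).
#' @param cycles cycle table in the same units as the hold levels.
#' @return the hold table with `rel_time_pos` (fraction of the exhalation
#'   duration elapsed at hold start) and `rel_amp_pos` (fraction of the
#'   exhalation amplitude descended at the hold level) appended, both
#'   clamped to `[0, 1]`.
#' @export
hold_position <- function(holds, cycles) {
  n <- nrow(holds)
  rt <- ra <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cy <- cycles[cycles$speaker == holds$speaker[i] &
                   cycles$cycle == holds$cycle[i], ]
    if (nrow(cy) != 1L) next
    dt <- cy$t_offset - cy$t_peak
    dv <- cy$v_peak - cy$v_offset
    if (dv <= 0 || dt <= 0) {
      stop("data error: zero-amplitude or zero-duration exhalation",
           call. = FALSE)
    }
    rt[i] <- (holds$t_start[i] - cy$t_peak) / dt
    ra[i] <- (cy$v_peak - holds$level[i]) / dv
  }
  holds$rel_time_pos <- pmin(1, pmax(0, rt))
  holds$rel_amp_pos <- pmin(1, pmax(0, ra))
  holds
}

#' Abandoned turn-initiation candidates
#'
#' Holds in the top portion of the exhalation amplitude (20% by default)
#' of cycles that do not overlap the speaker's own speech. The cut is
#' amplitude-based: how little of the exhalation amplitude has been
#' descended when the breath is held.
#'
#' @param cycles cycle table with the `silent` flag filled in (see
#'   [mark_silent_cycles()]).
#' @param holds silent-hold table (see [filter_silent_holds()]).
#' @param top_amp_frac amplitude fraction defining "top of the
#'   exhalation" (default 0.2).
#' @return the qualifying holds with their relative positions.
#' @export
abandoned_candidates <- function(cycles, holds, top_amp_frac = 0.2) {
  holds <- hold_position(holds, cycles)
  silent_key <- paste(cycles$speaker, cycles$cycle)[which(cycles$silent)]
  sel <- paste(holds$speaker, holds$cycle) %in% silent_key &
    !is.na(holds$rel_amp_pos) & holds$rel_amp_pos <= top_amp_frac
  out <- holds[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Speaker-change probability conditioned on a respiratory hold
#'
#' Over all non-excluded silence events (WSS and BSS), a hold co-occurs
#' with a silence when it overlaps the anchoring exhalation of the
#' previous speaker. The table reports the probability of a speaker
#' change (BSS) given the presence and given the absence of a hold; an
#' empty stratum yields `NA`.
#'
#' @param events event table after [apply_exclusions()].
#' @param holds silent-hold table.
#' @param cycles cycle table.
#' @param include_excluded also count excluded events (default FALSE).
#' @return an object of class `hold_condition_table`: counts
#'   `n_silence_with_hold`, `n_silence_without_hold`,
#'   `n_change_with_hold`, `n_change_without_hold` and probabilities
#'   `p_change_given_hold`, `p_change_given_no_hold`.
#' @export
speaker_change_given_hold <- function(events, holds, cycles,
                                      include_excluded = FALSE) {
  sil <- events[events$base %in% c("WSS", "BSS"), , drop = FALSE]
  if (!include_excluded) sil <- sil[is.na(sil$excluded), , drop = FALSE]
  has_hold <- vapply(seq_len(nrow(sil)), function(i) {
    if (is.na(sil$anchor_cycle[i])) return(FALSE)
    cy <- cycles[cycles$speaker == sil$prev_speaker[i] &
                   cycles$cycle == sil$anchor_cycle[i], ]
    h <- holds[holds$speaker == sil$prev_speaker[i], , drop = FALSE]
    any(h$t_start < cy$t_offset & h$t_end > cy$t_peak)
  }, logical(1))
  change <- sil$base == "BSS"
  tab <- list(
    n_silence_with_hold = sum(has_hold),
    n_silence_without_hold = sum(!has_hold),
    n_change_with_hold = sum(change & has_hold),
    n_change_without_hold = sum(change & !has_hold))
  tab$p_change_given_hold <-
    if (tab$n_silence_with_hold > 0) {
      tab$n_change_with_hold / tab$n_silence_with_hold
    } else NA_real_
  tab$p_change_given_no_hold <-
    if (tab$n_silence_without_hold > 0) {
      tab$n_change_without_hold / tab$n_silence_without_hold
    } else NA_real_
  structure(tab, class = "hold_condition_table")
}

#' @export
print.hold_condition_table <- function(x, ...) {
  cat("Speaker change conditioned on respiratory hold\n")
  cat(sprintf("  with hold:    P(change) = %s  (%d / %d)\n",
              format(x$p_change_given_hold, digits = 3),
              x$n_change_with_hold, x$n_silence_with_hold))
  cat(sprintf("  without hold: P(change) = %s  (%d / %d)\n",
              format(x$p_change_given_no_hold, digits = 3),
              x$n_change_without_hold, x$n_silence_without_hold))
  invisible(x)
}

#' Silent-cycle inhalation comparison groups
#'
#' Builds the three-group table contrasting pre-speech inhalations in
#' turn-taking cycles, TT(S), with inhalations of silent cycles that do
#' and do not carry an abandoned-initiation hold: groups `"TT(S)"`,
#' `"Hold"` and `"Silent"`. Inhalation duration (log2 s) and amplitude
#' (SV) feed the corresponding multinomial model.
#'
#' @param cycles cycle table in SV units with `silent` flags.
#' @param candidates abandoned-candidate table from
#'   [abandoned_candidates()].
#' @param tt TT event table from [tt_events()] (only non-excluded TT(S)
#'   rows are used).
#' @param floor_s duration floor before log2.
#' @return data.frame with columns `group`, `speaker`, `cycle`,
#'   `inh_duration_log2s`, `inh_amplitude`.
#' @export
silent_cycle_groups <- function(cycles, candidates, tt, floor_s = 0.01) {
  key <- function(sp, cy) paste(sp, cy)
  tts <- tt[tt$kind == "TT(S)" & is.na(tt$excluded), , drop = FALSE]
  tt_key <- key(tts$speaker, tts$inh_cycle)
  cand_key <- unique(key(candidates$speaker, candidates$cycle))
  rows <- list()
  add <- function(cy, group) {
    data.frame(group = group, speaker = cy$speaker, cycle = cy$cycle,
               inh_duration_log2s = log2_dur(cy$t_peak - cy$t_onset, floor_s),
               inh_amplitude = cy$v_peak - cy$v_onset,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(cycles))) {
    cy <- cycles[i, ]
    k <- key(cy$speaker, cy$cycle)
    if (k %in% tt_key) {
      rows[[length(rows) + 1L]] <- add(cy, "TT(S)")
    } else if (isTRUE(cy$silent)) {
      rows[[length(rows) + 1L]] <-
        add(cy, if (k %in% cand_key) "Hold" else "Silent")
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(group = character(), speaker = character(),
                      cycle = integer(), inh_duration_log2s = numeric(),
                      inh_amplitude = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
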