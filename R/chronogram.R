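#' Interaction chronography
#'
#' Talkspurts (interpausal units) are stretches of one speaker's voice
#' activity delimited by pauses longer than a threshold (200 ms by
#' default). The chronogram classifies every interactional interval by two
#' criteria -- presence of overlapping speech and presence of speaker
#' change -- into within-speaker silence (WSS), within-speaker overlap
#' (WSO), between-speaker silence (BSS) and between-speaker overlap (BSO).
#' WSS, BSS and BSO are further augmented by whether the previous speaker
#' inhales before their own next talkspurt (+INH) or continues on the same
#' exhalation (-INH). All intervals are half-open `[start, end)` in
#' seconds.
#'
#' @name chronography
NULL

#' Merge raw speech-activity intervals into talkspurts
#'
#' Same-speaker intervals separated by less than `min_pause_s` are merged.
#' Talkspurts shorter than `backchannel_s` (1 s) are flagged as
#' backchannels.
#'
#' @param intervals data.frame with columns `speaker`, `t_start`, `t_end`
#'   (raw voice-activity intervals, non-overlapping within speaker).
#' @param min_pause_s minimum pause between two adjacent talkspurts
#'   (default 0.2 s); shorter gaps are merged.
#' @param backchannel_s duration threshold under which a talkspurt counts
#'   as a backchannel (default 1 s).
#' @return data.frame with one row per talkspurt: `ts`, `speaker`,
#'   `t_start`, `t_end`, `is_backchannel`, `contains_laughter` (FALSE
#'   until [flag_laughter()] is applied), ordered by onset.
#' @export
merge_talkspurts <- function(intervals, min_pause_s = 0.2, backchannel_s = 1.0) {
  stopifnot(all(c("speaker", "t_start", "t_end") %in% names(intervals)))
  if (any(intervals$t_end <= intervals$t_start)) {
    stop("input intervals must have t_end > t_start", call. = FALSE)
  }
  parts <- lapply(split(intervals, intervals$speaker), function(d) {
    d <- d[order(d$t_start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$t_start[-1L] < d$t_end[-nrow(d)])) {
      stop(sprintf("overlapping input intervals for speaker %s", d$speaker[1L]),
           call. = FALSE)
    }
    s <- d$t_start; e <- d$t_end
    if (nrow(d) > 1L) {
      new_grp <- c(TRUE, s[-1L] - e[-length(e)] >= min_pause_s)
      grp <- cumsum(new_grp)
      s <- tapply(s, grp, min)
      e <- tapply(e, grp, max)
    }
    data.frame(speaker = d$speaker[1L], t_start = as.numeric(s),
               t_end = as.numeric(e), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$t_start, out$t_end), , drop = FALSE]
  rownames(out) <- NULL
  out$is_backchannel <- (out$t_end - out$t_start) < backchannel_s
  out$contains_laughter <- FALSE
  out <- cbind(ts = seq_len(nrow(out)), out)
  out
}

#' Flag talkspurts that overlap laughter
#'
#' @param talkspurts talkspurt table from [merge_talkspurts()].
#' @param laughter data.frame with `speaker`, `t_start`, `t_end`; a
#'   talkspurt is flagged when it has any positive temporal intersection
#'   with a laughter interval of its own speaker.
#' @return the talkspurt table with `contains_laughter` updated.
#' @export
flag_laughter <- function(talkspurts, laughter) {
  if (is.null(laughter) || nrow(laughter) == 0L) return(talkspurts)
  talkspurts$contains_laughter <- vapply(seq_len(nrow(talkspurts)), function(i) {
    la <- laughter[laughter$speaker == talkspurts$speaker[i], , drop = FALSE]
    any(la$t_start < talkspurts$t_end[i] & la$t_end > talkspurts$t_start[i])
  }, logical(1))
  talkspurts
}

#' Classify interactional intervals into chronogram categories
#'
#' Silence events (WSS, BSS) are the maximal gaps in the union of all
#' speakers' talkspurts, bounded by the talkspurt ending at the gap start
#' and the talkspurt starting at the gap end (ties broken toward the
#' longer talkspurt). Overlap events are computed pairwise: a talkspurt
#' fully inside another speaker's talkspurt is a within-speaker overlap
#' (the floor stays with the outer speaker); a talkspurt that starts
#' during another's and outlasts it is a between-speaker overlap over the
#' overlapped span.
#'
#' @param talkspurts talkspurt table from [merge_talkspurts()].
#' @return data.frame with one row per event: `event`, `base`
#'   (WSS/WSO/BSS/BSO), `inh` (`NA` until [augment_inh()]),
#'   `prev_speaker`, `next_speaker`, `t_start`, `t_end`, `prev_ts`,
#'   `next_ts` (row ids of the bounding talkspurts; for WSO, `prev_ts` is
#'   the outer and `next_ts` the inner talkspurt), `excluded` (`NA`).
#' @export
classify_intervals <- function(talkspurts) {
  ts <- talkspurts[order(talkspurts$t_start, -(talkspurts$t_end)), , drop = FALSE]
  rows <- list()
  # --- global silences -------------------------------------------------
  if (nrow(ts) > 1L) {
    # union sweep
    block_end <- ts$t_end[1L]
    for (i in 2:nrow(ts)) {
      if (ts$t_start[i] > block_end) {
        gap_s <- block_end; gap_e <- ts$t_start[i]
        prev_cand <- ts[abs(ts$t_end - gap_s) < 1e-9, , drop = FALSE]
        next_cand <- ts[abs(ts$t_start - gap_e) < 1e-9, , drop = FALSE]
        prev <- prev_cand[which.max(prev_cand$t_end - prev_cand$t_start), ]
        nxt <- next_cand[which.max(next_cand$t_end - next_cand$t_start), ]
        rows[[length(rows) + 1L]] <- data.frame(
          base = if (prev$speaker == nxt$speaker) "WSS" else "BSS",
          prev_speaker = prev$speaker, next_speaker = nxt$speaker,
          t_start = gap_s, t_end = gap_e,
          prev_ts = prev$ts, next_ts = nxt$ts, stringsAsFactors = FALSE)
      }
      block_end <- max(block_end, ts$t_end[i])
    }
  }
  # --- overlaps (pairwise) --------------------------------------------
  if (nrow(ts) > 1L) {
    for (i in seq_len(nrow(ts) - 1L)) {
      for (j in (i + 1L):nrow(ts)) {
        if (ts$t_start[j] >= ts$t_end[i]) break
        if (ts$speaker[j] == ts$speaker[i]) next
        if (ts$t_end[j] <= ts$t_end[i]) {
          # j fully inside i: within-speaker overlap, floor stays with i
          rows[[length(rows) + 1L]] <- data.frame(
            base = "WSO",
            prev_speaker = ts$speaker[i], next_speaker = ts$speaker[i],
            t_start = ts$t_start[j], t_end = ts$t_end[j],
            prev_ts = ts$ts[i], next_ts = ts$ts[j], stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            base = "BSO",
            prev_speaker = ts$speaker[i], next_speaker = ts$speaker[j],
            t_start = ts$t_start[j], t_end = ts$t_end[i],
            prev_ts = ts$ts[i], next_ts = ts$ts[j], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(event = integer(), base = character(), inh = character(),
                      prev_speaker = character(), next_speaker = character(),
                      t_start = numeric(), t_end = numeric(),
                      prev_ts = integer(), next_ts = integer(),
                      excluded = character(), stringsAsFactors = FALSE))
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$t_start, ev$t_end), , drop = FALSE]
  rownames(ev) <- NULL
  cbind(event = seq_len(nrow(ev)),
        ev[, "base", drop = FALSE],
        inh = NA_character_,
        ev[, c("prev_speaker", "next_speaker", "t_start", "t_end",
               "prev_ts", "next_ts")],
        excluded = NA_character_)
}

#' Augment events with the previous speaker's inhalation status
#'
#' For every WSS, BSS and BSO event, `inh` is `"plus"` when an inhalation
#' onset of the previous speaker occurs strictly between the offset of the
#' event-anchoring talkspurt and the onset of that speaker's next
#' talkspurt, `"minus"` when the next talkspurt directly continues the
#' same exhalation, and `"na"` (with the event excluded) when the previous
#' speaker never speaks again. WSO events keep `inh = "na"`.
#'
#' @param events event table from [classify_intervals()].
#' @param cycles cycle table covering all speakers that appear as
#'   `prev_speaker` (rows are matched by the `speaker` column).
#' @param talkspurts the talkspurt table the events were built from.
#' @return the event table with `inh` filled in and two helper columns:
#'   `next_own_onset` (onset of the previous speaker's next talkspurt) and
#'   `inh_cycle` (the cycle whose inhalation precedes it, for `+INH`).
#' @export
augment_inh <- function(events, cycles, talkspurts) {
  events$next_own_onset <- NA_real_
  events$inh_cycle <- NA_integer_
  for (i in seq_len(nrow(events))) {
    if (!events$base[i] %in% c("WSS", "BSS", "BSO")) {
      events$inh[i] <- "na"
      next
    }
    sp <- events$prev_speaker[i]
    cyc <- cycles[cycles$speaker == sp, , drop = FALSE]
    if (nrow(cyc) == 0L) {
      stop(sprintf("no breathing cycles available for speaker %s", sp),
           call. = FALSE)
    }
    anchor_off <- talkspurts$t_end[match(events$prev_ts[i], talkspurts$ts)]
    own <- talkspurts[talkspurts$speaker == sp &
                        talkspurts$t_start > anchor_off, , drop = FALSE]
    if (nrow(own) == 0L) {
      events$inh[i] <- "na"
      if (is.na(events$excluded[i])) events$excluded[i] <- "no_next_talkspurt"
      next
    }
    nxt_on <- min(own$t_start)
    events$next_own_onset[i] <- nxt_on
    between <- cyc$t_onset > anchor_off & cyc$t_onset < nxt_on
    if (any(between)) {
      events$inh[i] <- "plus"
      events$inh_cycle[i] <- cyc$cycle[max(which(between))]
    } else {
      events$inh[i] <- "minus"
    }
  }
  events
}

# category label string, e.g. "BSS+INH"
event_category <- function(events) {
  ifelse(events$base == "WSO", "WSO",
         paste0(events$base,
                ifelse(events$inh == "plus", "+INH",
                       ifelse(events$inh == "minus", "-INH", ""))))
}

# cycle of `speaker` whose exhalation [t_peak, t_offset) contains time t
find_exhalation <- function(cycles, speaker, t) {
  cyc <- cycles[cycles$speaker == speaker, , drop = FALSE]
  hit <- which(cyc$t_peak <= t & t < cyc$t_offset)
  if (length(hit) == 0L) return(NA_integer_)
  cyc$cycle[hit[1L]]
}

#' Apply the exclusion filters to an event table
#'
#' Exclusion reasons, assigned in this order (first match wins):
#' `edge_inhalation` when either bounding talkspurt edge falls inside an
#' inhalation of its own speaker; `laughter` when the event interval or a
#' bounding talkspurt overlaps laughter; `backchannel` when a bounding
#' talkspurt is shorter than the backchannel threshold; and
#' `missed_inhalation_suspect` for `-INH` events whose anchoring
#' exhalation lasts longer than twice the speaker's median cycle duration
#' (an automatic proxy for a manual missed-inhalation check: implausibly
#' long exhalations usually hide an undetected small inhalation).
#'
#' @param events event table from [augment_inh()].
#' @param talkspurts talkspurt table (with laughter flags, see
#'   [flag_laughter()]).
#' @param cycles cycle table for all speakers.
#' @param laughter optional laughter interval table (`speaker`, `t_start`,
#'   `t_end`); intersected with the event span regardless of speaker.
#' @return the event table with `excluded` filled in and an
#'   `anchor_cycle` column (the cycle whose exhalation contains the
#'   anchoring talkspurt offset).
#' @export
apply_exclusions <- function(events, talkspurts, cycles, laughter = NULL) {
  events$anchor_cycle <- NA_integer_
  med_cyc <- vapply(split(cycles, cycles$speaker),
                    function(d) stats::median(d$t_offset - d$t_onset),
                    numeric(1))
  in_inhalation <- function(sp, t) {
    cyc <- cycles[cycles$speaker == sp, , drop = FALSE]
    any(cyc$t_onset < t & t < cyc$t_peak)
  }
  overlaps_laughter <- function(a, b) {
    if (is.null(laughter) || nrow(laughter) == 0L) return(FALSE)
    any(laughter$t_start < b & laughter$t_end > a)
  }
  for (i in seq_len(nrow(events))) {
    prev <- talkspurts[match(events$prev_ts[i], talkspurts$ts), ]
    nxt <- talkspurts[match(events$next_ts[i], talkspurts$ts), ]
    if (events$base[i] != "WSO") {
      events$anchor_cycle[i] <- find_exhalation(cycles, prev$speaker, prev$t_end)
    }
    if (!is.na(events$excluded[i])) next
    if (in_inhalation(prev$speaker, prev$t_end) ||
        in_inhalation(nxt$speaker, nxt$t_start)) {
      events$excluded[i] <- "edge_inhalation"
    } else if (overlaps_laughter(events$t_start[i], events$t_end[i]) ||
               overlaps_laughter(prev$t_start, prev$t_end) ||
               overlaps_laughter(nxt$t_start, nxt$t_end) ||
               isTRUE(prev$contains_laughter) || isTRUE(nxt$contains_laughter)) {
      events$excluded[i] <- "laughter"
    } else if (isTRUE(prev$is_backchannel) || isTRUE(nxt$is_backchannel)) {
      events$excluded[i] <- "backchannel"
    } else if (identical(events$inh[i], "minus") &&
               !is.na(events$anchor_cycle[i])) {
      cyc <- cycles[cycles$speaker == events$prev_speaker[i] &
                      cycles$cycle == events$anchor_cycle[i], ]
      if ((cyc$t_offset - cyc$t_peak) > 2 * med_cyc[[events$prev_speaker[i]]]) {
        events$excluded[i] <- "missed_inhalation_suspect"
      }
    }
  }
  events
}

#' Turn-initial talkspurts of incoming speakers
#'
#' A talkspurt is turn-incoming when its speaker differs from the most
#' recent speaker: either its onset overlaps another speaker's ongoing
#' talkspurt, giving TT(O), or it follows silence across all speakers and
#' the last talkspurt to end before it belongs to someone else, giving
#' TT(S). Each event links the immediately preceding inhalation of the
#' incoming speaker (the talkspurt must start during that cycle's
#' exhalation, otherwise no event is produced).
#'
#' @param talkspurts talkspurt table from [merge_talkspurts()].
#' @param cycles cycle table for all speakers.
#' @return data.frame with one row per turn-initial talkspurt: `kind`
#'   (`"TT(S)"` or `"TT(O)"`), `speaker` (incoming), `ts` (talkspurt id),
#'   `t_start`, `inh_cycle` (the linked cycle), `excluded`.
#' @export
tt_events <- function(talkspurts, cycles) {
  ts <- talkspurts[order(talkspurts$t_start), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(ts))) {
    on <- ts$t_start[i]
    sp <- ts$speaker[i]
    active <- ts$speaker != sp & ts$t_start < on & ts$t_end > on
    if (any(active)) {
      kind <- "TT(O)"
    } else {
      before <- ts[ts$t_end <= on + 1e-9 & ts$ts != ts$ts[i], , drop = FALSE]
      if (nrow(before) == 0L) next
      last <- before[which.max(before$t_end), ]
      if (last$speaker == sp) next
      kind <- "TT(S)"
    }
    cyc <- cycles[cycles$speaker == sp, , drop = FALSE]
    hit <- which(cyc$t_peak <= on & on < cyc$t_offset)
    if (length(hit) == 0L) next
    excl <- NA_character_
    if (isTRUE(ts$contains_laughter[i])) excl <- "laughter"
    else if (isTRUE(ts$is_backchannel[i])) excl <- "backchannel"
    rows[[length(rows) + 1L]] <- data.frame(
      kind = kind, speaker = sp, ts = ts$ts[i], t_start = on,
      inh_cycle = cyc$cycle[hit[1L]], excluded = excl,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(kind = character(), speaker = character(),
                      ts = integer(), t_start = numeric(),
                      inh_cycle = integer(), excluded = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
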