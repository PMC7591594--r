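#' Synthetic multiparty conversations with ground truth
#'
#' The generator emits what the analysis pipeline consumes -- one RIP
#' trace per speaker plus speech-activity intervals -- together with the
#' ground truth it was built from: breathing-cycle landmarks, planted
#' plateau holds, talkspurts and the derived interactional labels. Turns
#' are drawn from a semi-Markov speaker process; each speaking exhalation
#' hosts one or more talkspurts (a within-speaker continuation on the same
#' exhalation realises a -INH interval, an intervening inhalation a +INH
#' interval); interjections by another speaker during an ongoing
#' exhalation realise BSS-INH/BSO-INH pause interruptions. Listeners
#' breathe quiet cycles with a longer-inhalation, more symmetric shape.
#' Holds are planted as exact plateaus and the whole trace is rendered
#' piecewise linearly, corner-smoothed with a 100-ms Hann kernel and
#' noised.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults mirror the study conditions the pipeline targets: three-party
#' casual conversations of about 20 minutes, a category mix in which
#' roughly 70% of within-speaker silences are -INH, a third of speaker
#' changes involve overlap and pause interruptions are rare, per-category
#' hold co-occurrence rates of a few percent (highest for -INH
#' between-speaker intervals), and silent-cycle holds that are bimodal
#' within the exhalation, with the smaller mode near the top.
#'
#' @param n_speakers number of speakers (default 3).
#' @param duration_s conversation length in seconds (default 1200).
#' @param sample_rate_hz trace sample rate (default 100).
#' @param noise_sd sensor noise SD as a fraction of the mean breathing
#'   cycle amplitude (default 0.02).
#' @param overlap_prob probability that a speaker change involves overlap
#'   (default 0.33).
#' @param p_continue probability of another talkspurt within the turn
#'   (default 0.62, echoing the observed within- to between-speaker
#'   interval ratio).
#' @param p_wss_inh probability that a within-turn continuation is
#'   preceded by an inhalation (default 0.22).
#' @param p_interrupt probability that a silence speaker change is a
#'   pause interruption, i.e. the original speaker resumes on the same
#'   exhalation (BSS-INH; default 0.07).
#' @param p_bso_minus the same for overlapped changes (BSO-INH; default
#'   0.14).
#' @param backchannel_prob probability of a listener backchannel per turn
#'   (default 0.10).
#' @param laughter_prob probability of a laughter interval per turn
#'   (default 0.05).
#' @param hold_rates named vector of hold-planting probabilities on the
#'   anchoring exhalation per interval category.
#' @param silent_hold_prob hold probability per quiet (listener) cycle
#'   (default 0.08).
#' @param silent_hold_top_frac fraction of silent holds planted near the
#'   top of the exhalation (default 0.25, the smaller of the two modes).
#' @param hold_duration_s range of planted hold durations (default
#'   0.35-0.8 s).
#' @param seed optional RNG seed stored with the config.
#' @param ... overrides for the remaining kinematic parameters (see the
#'   source for the full list: talkspurt, pause, gap, overlap and
#'   quiet/speech breathing duration and level distributions).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_speakers = 3, duration_s = 1200, sample_rate_hz = 100,
                       noise_sd = 0.02, overlap_prob = 0.33,
                       p_continue = 0.62, p_wss_inh = 0.22,
                       p_interrupt = 0.07, p_bso_minus = 0.14,
                       backchannel_prob = 0.10, laughter_prob = 0.05,
                       hold_rates = c("WSS-INH" = 0.02, "WSS+INH" = 0.01,
                                      "BSS-INH" = 0.10, "BSS+INH" = 0.06,
                                      "BSO-INH" = 0.08, "BSO+INH" = 0.03),
                       silent_hold_prob = 0.08, silent_hold_top_frac = 0.25,
                       hold_duration_s = c(0.35, 0.8),
                       seed = NULL, ...) {
  cfg <- list(
    n_speakers = n_speakers, duration_s = duration_s,
    sample_rate_hz = sample_rate_hz, noise_sd = noise_sd,
    overlap_prob = overlap_prob, p_continue = p_continue,
    p_wss_inh = p_wss_inh, p_interrupt = p_interrupt,
    p_bso_minus = p_bso_minus, backchannel_prob = backchannel_prob,
    laughter_prob = laughter_prob, hold_rates = hold_rates,
    silent_hold_prob = silent_hold_prob,
    silent_hold_top_frac = silent_hold_top_frac,
    hold_duration_s = hold_duration_s, seed = seed,
    # talkspurts and interaction timing
    talkspurt_meanlog = log(2.2), talkspurt_sdlog = 0.45,
    talkspurt_range_s = c(1.05, 6), max_talkspurts = 4L,
    pause_minus_s = c(0.30, 0.80), pause_minus_hold_s = c(0.70, 1.10),
    tail_plus_s = c(0.15, 0.35), tail_plus_hold_s = c(0.95, 1.30),
    gap_bss_s = c(0.45, 0.15, 0.25, 1.0),      # mean, sd, min, max
    overlap_s = c(0.30, 0.80),
    interject_s = c(1.0, 2.2), interject_gap_s = c(0.30, 0.60),
    backchannel_s = c(0.5, 0.9),
    # breathing kinematics (raw units on a 0-1 scale); within-turn
    # inhalations are shorter and quicker into speech than turn-initial
    # ones (temporal compression of the turn-holding breath pause)
    inh_cont_s = c(0.50, 0.10, 0.32, 0.75),
    inh_init_s = c(0.72, 0.18, 0.45, 1.20),
    lag_cont_s = c(0.10, 0.25),
    lag_init_s = c(0.12, 0.38),
    quiet_inh_s = c(0.68, 0.18, 0.42, 1.20),
    quiet_exh_s = c(2.6, 0.40, 1.7, 3.8),
    quiet_amp = c(0.52, 0.08, 0.35, 0.68),
    top_hold_inh_gain = c(1.25, 1.15),  # duration/amplitude scaling before
                                        # an abandoned-initiation hold
    speech_peak = c(0.78, 0.06, 0.65, 0.92),
    rel_base = c(0.17, 0.02), rel_jitter_sd = 0.012,
    minus_offset = c(0.24, 0.06, 0.10, 0.38),  # raised trough after -INH
    plus_offset_max = 0.05,
    pause_weight = 0.30, silence_weight = 0.25,
    top_amp_range = c(0.03, 0.18), bottom_amp_range = c(0.78, 0.92),
    smooth_s = 0.06)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

rnormt <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}
rpar <- function(p) rnormt(1, p[1], p[2], p[3], p[4])
rrange <- function(r) stats::runif(1, r[1], r[2])

#' Simulate one conversation
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (overrides `config$seed`); the output is
#'   deterministic given the seed.
#' @return an object of class `breathturn_sim`: a list with `traces`
#'   (named list of raw [rip_trace()]s), `intervals` (speech-activity
#'   table: `speaker`, `t_start`, `t_end`), `laughter`, and
#'   `ground_truth` holding `cycles`, `holds` (with `top` flags),
#'   `talkspurts`, `events`, `tt` and `abandoned` -- the labels are
#'   derived from the planted landmarks with the package's own
#'   classification logic, so they are consistent with the emitted traces
#'   by construction.
#' @export
simulate_conversation <- function(config = sim_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  speakers <- paste0("S", seq_len(cfg$n_speakers))
  if (cfg$n_speakers < 2L) stop("config error: need at least 2 speakers",
                                call. = FALSE)
  if (exp(cfg$talkspurt_meanlog) >= cfg$duration_s / 4) {
    stop("config error: talkspurts too long for the conversation duration",
         call. = FALSE)
  }

  rel_of <- stats::setNames(rnormt(cfg$n_speakers, cfg$rel_base[1],
                                   cfg$rel_base[2], 0.10, 0.26), speakers)
  trough <- function(sp) rel_of[[sp]] + stats::rnorm(1, 0, cfg$rel_jitter_sd)

  # per-speaker accumulators
  cycles <- list()       # cycle specs (list of lists)
  talkspurts <- list()   # (speaker, t_start, t_end)
  laughter <- list()
  holds_gt <- list()     # planted holds (speaker, t_start, t_end, level, top)
  prev_end <- stats::setNames(rep(1, cfg$n_speakers), speakers)   # last trough time
  prev_val <- stats::setNames(vapply(speakers, trough, numeric(1)), speakers)

  add_ts <- function(sp, s, e) {
    talkspurts[[length(talkspurts) + 1L]] <<- data.frame(
      speaker = sp, t_start = s, t_end = e, stringsAsFactors = FALSE)
  }
  add_hold <- function(sp, s, e, level, top) {
    holds_gt[[length(holds_gt) + 1L]] <<- data.frame(
      speaker = sp, t_start = s, t_end = e, level = level, top = top,
      stringsAsFactors = FALSE)
  }
  add_cycle <- function(sp, t_on, v_on, t_peak, v_peak, exh_bp) {
    cycles[[length(cycles) + 1L]] <<- list(
      speaker = sp, t_onset = t_on, v_onset = v_on,
      t_peak = t_peak, v_peak = v_peak, exh = exh_bp)
  }

  draw_ts_dur <- function() {
    min(max(stats::rlnorm(1, cfg$talkspurt_meanlog, cfg$talkspurt_sdlog),
            cfg$talkspurt_range_s[1]), cfg$talkspurt_range_s[2])
  }

  # ---- quiet fill: listener breathing over [a, b], start value v_a ----
  quiet_fill <- function(sp, a, b, v_a, v_b) {
    gap <- b - a
    if (gap < 1e-9) return(v_a)
    nominal <- cfg$quiet_inh_s[1] + cfg$quiet_exh_s[1]
    n <- max(1L, round(gap / nominal))
    for (attempt in 1:3) {
      di <- rnormt(n, cfg$quiet_inh_s[1], cfg$quiet_inh_s[2],
                   cfg$quiet_inh_s[3], cfg$quiet_inh_s[4])
      de <- rnormt(n, cfg$quiet_exh_s[1], cfg$quiet_exh_s[2],
                   cfg$quiet_exh_s[3], cfg$quiet_exh_s[4])
      has_hold <- stats::runif(n) < cfg$silent_hold_prob
      hold_top <- has_hold & stats::runif(n) < cfg$silent_hold_top_frac
      hd <- ifelse(has_hold, stats::runif(n, cfg$hold_duration_s[1],
                                          cfg$hold_duration_s[2]), 0)
      di <- ifelse(hold_top, di * cfg$top_hold_inh_gain[1], di)
      scale <- (gap - sum(hd)) / sum(di + de)
      if (scale >= 0.6 && scale <= 1.75) break
      n <- max(1L, n + ifelse(scale > 1, 1L, -1L))
    }
    scale <- (gap - sum(hd)) / sum(di + de)
    if (scale <= 0) { has_hold[] <- FALSE; hd[] <- 0
                      scale <- gap / sum(di + de) }
    di <- di * scale; de <- de * scale
    t <- a; v <- v_a
    for (i in seq_len(n)) {
      amp <- rpar(cfg$quiet_amp)
      if (hold_top[i]) amp <- amp * cfg$top_hold_inh_gain[2]
      v_pk <- v + amp
      v_tr <- if (i == n) v_b else trough(sp)
      t_pk <- t + di[i]
      t_end <- t_pk + de[i] + hd[i]
      if (has_hold[i] && de[i] > 0.9) {
        top <- hold_top[i]
        r <- if (top) rrange(cfg$top_amp_range) else rrange(cfg$bottom_amp_range)
        lvl <- v_pk - r * (v_pk - v_tr)
        # keep real ramps on both sides of the plateau so that the hold
        # stands clear of the cycle's own turning points
        pre <- min(max(r * de[i], 0.25), de[i] - 0.30)
        post <- de[i] - pre
        bp <- data.frame(t = c(t_pk, t_pk + pre, t_pk + pre + hd[i], t_end),
                         v = c(v_pk, lvl, lvl, v_tr))
        add_hold(sp, t_pk + pre, t_pk + pre + hd[i], lvl, top)
      } else {
        bp <- data.frame(t = c(t_pk, t_end), v = c(v_pk, v_tr))
      }
      add_cycle(sp, t, v, t_pk, v_pk, bp)
      t <- t_end; v <- v_tr
    }
    v
  }

  # ---- speech exhalation builder ----
  # segs: data.frame(t0, t1, w, hold). Holds stay exactly flat; silent
  # segments (pauses, interruptions, tails) keep a minimum slope of
  # min_sil_slope * amplitude per second so that a slow exhalation never
  # mimics a plateau; talkspurts absorb the remaining descent in
  # proportion to their weighted duration.
  close_exhalation <- function(sp, t_exh_start, v_pk, segs, v_off,
                               min_sil_slope = 0.2) {
    amp <- v_pk - v_off
    dur <- segs$t1 - segs$t0
    is_hold <- segs$hold | segs$w <= 0
    is_sil <- !is_hold & segs$w < 1
    base <- amp * segs$w * dur / max(sum(segs$w * dur), 1e-12)
    d_sil <- pmax(base, min_sil_slope * amp * dur) * is_sil
    if (sum(d_sil) > 0.8 * amp) d_sil <- d_sil * 0.8 * amp / sum(d_sil)
    rem <- amp - sum(d_sil)
    wspeech <- segs$w * dur * (!is_hold & !is_sil)
    if (sum(wspeech) > 0) {
      d_sp <- rem * wspeech / sum(wspeech)
    } else {
      d_sp <- rep(0, nrow(segs))
      if (sum(d_sil) > 0) d_sil <- d_sil * amp / sum(d_sil)
    }
    drops <- ifelse(is_hold, 0, ifelse(is_sil, d_sil, d_sp))
    data.frame(t = c(t_exh_start, segs$t1),
               v = v_pk - cumsum(c(0, drops)))
  }

  # plant a hold inside a silent span [s0, s1]; returns updated seg rows
  hold_segs <- function(sp, s0, s1, w) {
    hd <- min(rrange(cfg$hold_duration_s), s1 - s0 - 0.4)
    if (hd < 0.30) {
      return(data.frame(t0 = s0, t1 = s1, w = w, hold = FALSE))
    }
    m <- stats::runif(1, 0.15, s1 - s0 - hd - 0.2)
    data.frame(t0 = c(s0, s0 + m, s0 + m + hd),
               t1 = c(s0 + m, s0 + m + hd, s1),
               w = c(w, 0, w), hold = c(FALSE, TRUE, FALSE))
  }

  # ---- floor process ----
  t_now <- 8
  spk <- sample(speakers, 1L)
  guard <- 0L
  while (t_now < cfg$duration_s - 25 && guard < 10000L) {
    guard <- guard + 1L
    # schedule turn for spk with first talkspurt at ~t_now
    d_inh <- rpar(cfg$inh_init_s)
    lag <- rrange(cfg$lag_init_s)
    t_inh_on <- t_now - lag - d_inh
    if (t_inh_on < prev_end[[spk]] + 1.2) {
      # too close to the speaker's previous cycle: merge, lengthening the
      # pre-speech inhalation (or push the onset if even that is too tight)
      if (t_now - lag - prev_end[[spk]] < 0.4) {
        t_now <- prev_end[[spk]] + 0.4 + lag
      }
      t_inh_on <- prev_end[[spk]]
      v_on <- prev_val[[spk]]
    } else {
      v_on <- trough(spk)
      prev_val[[spk]] <- quiet_fill(spk, prev_end[[spk]], t_inh_on,
                                    prev_val[[spk]], v_on)
    }
    t_exh_start <- t_now - lag
    v_pk <- max(rpar(cfg$speech_peak), v_on + 0.30)

    segs <- data.frame(t0 = t_inh_on + d_inh, t1 = t_now,
                       w = cfg$pause_weight, hold = FALSE)
    # guard against numeric degeneracy when lag is tiny
    segs <- segs[segs$t1 > segs$t0, , drop = FALSE]
    hosts_minus <- FALSE
    turn_ts <- list()
    e <- t_now
    n_ts <- 0L
    resumed <- FALSE
    repeat {
      d1 <- draw_ts_dur()
      add_ts(spk, e, e + d1)
      turn_ts[[length(turn_ts) + 1L]] <- c(e, e + d1)
      segs <- rbind(segs, data.frame(t0 = e, t1 = e + d1, w = 1, hold = FALSE))
      e <- e + d1
      n_ts <- n_ts + 1L
      if (n_ts >= cfg$max_talkspurts || resumed ||
          stats::runif(1) >= cfg$p_continue) break
      # at most one same-exhalation continuation before an inhalation is
      # forced: keeps -INH exhalation durations physiologically plausible
      if (stats::runif(1) < cfg$p_wss_inh || hosts_minus) {
        # WSS+INH: close this exhalation, inhale, continue on a new one
        plant <- !hosts_minus &&
          stats::runif(1) < 2 * cfg$hold_rates[["WSS+INH"]]
        tail <- if (plant) rrange(cfg$tail_plus_hold_s) else rrange(cfg$tail_plus_s)
        sg <- if (plant) hold_segs(spk, e, e + tail, cfg$silence_weight)
              else data.frame(t0 = e, t1 = e + tail, w = cfg$silence_weight,
                              hold = FALSE)
        segs <- rbind(segs, sg)
        v_off <- rel_of[[spk]] + stats::runif(1, 0, cfg$plus_offset_max)
        bp <- close_exhalation(spk, t_exh_start, v_pk, segs, v_off)
        emit_speech_cycle(sp = spk, t_inh_on, v_on, t_exh_start, v_pk, bp,
                          segs, add_cycle, add_hold)
        # new cycle
        t_inh_on <- e + tail
        v_on <- v_off
        d_inh2 <- rpar(cfg$inh_cont_s)
        lag2 <- rrange(cfg$lag_cont_s)
        t_exh_start <- t_inh_on + d_inh2
        v_pk <- max(rpar(cfg$speech_peak), v_on + 0.30)
        e <- t_exh_start + lag2
        segs <- data.frame(t0 = t_exh_start, t1 = e, w = cfg$pause_weight,
                           hold = FALSE)
        hosts_minus <- FALSE
      } else {
        # WSS-INH: pause on the same exhalation
        plant <- stats::runif(1) < cfg$hold_rates[["WSS-INH"]]
        p <- if (plant) rrange(cfg$pause_minus_hold_s) else rrange(cfg$pause_minus_s)
        sg <- if (plant) hold_segs(spk, e, e + p, cfg$pause_weight)
              else data.frame(t0 = e, t1 = e + p, w = cfg$pause_weight,
                              hold = FALSE)
        segs <- rbind(segs, sg)
        hosts_minus <- TRUE
        e <- e + p
      }
    }

    # backchannel / laughter decoration of this turn (backchannels only in
    # non-final talkspurts, so they cannot collide with the next turn)
    long_ts <- Filter(function(x) x[2] - x[1] >= 1.8,
                      turn_ts[-length(turn_ts)])
    if (length(long_ts) > 0L && stats::runif(1) < cfg$backchannel_prob) {
      host <- long_ts[[sample(length(long_ts), 1L)]]
      cand <- setdiff(speakers, spk)
      cand <- cand[prev_end[cand] <= host[1] - 2]
      if (length(cand) > 0L) {
        bsp <- sample(cand, 1L)
        bd <- rrange(cfg$backchannel_s)
        b0 <- stats::runif(1, host[1] + 0.3, host[2] - bd - 0.3)
        add_ts(bsp, b0, b0 + bd)
      }
    }
    if (stats::runif(1) < cfg$laughter_prob && length(turn_ts) > 0L) {
      host <- turn_ts[[sample(length(turn_ts), 1L)]]
      ld <- stats::runif(1, 0.3, 0.6)
      laughter[[length(laughter) + 1L]] <- data.frame(
        speaker = spk, t_start = host[2] - ld, t_end = host[2],
        stringsAsFactors = FALSE)
    }

    # ---- transition ----
    nxt <- sample(setdiff(speakers, spk), 1L)
    last_d <- turn_ts[[length(turn_ts)]][2] - turn_ts[[length(turn_ts)]][1]
    overlap <- stats::runif(1) < cfg$overlap_prob && last_d > 1.1
    if (overlap) {
      ov <- min(rrange(cfg$overlap_s), last_d - 0.25)
      nxt_on <- e - ov
      minus <- stats::runif(1) < cfg$p_bso_minus
      cat_plus <- "BSO+INH"; cat_minus <- "BSO-INH"
    } else {
      g <- rnormt(1, cfg$gap_bss_s[1], cfg$gap_bss_s[2],
                  cfg$gap_bss_s[3], cfg$gap_bss_s[4])
      nxt_on <- e + g
      minus <- stats::runif(1) < cfg$p_interrupt
      cat_plus <- "BSS+INH"; cat_minus <- "BSS-INH"
    }
    if (minus && t_now < cfg$duration_s - 60) {
      # pause interruption: `nxt` produces one talkspurt, spk resumes on
      # the same exhalation
      dI <- rrange(cfg$interject_s)
      # interjector's own mini-episode (pre-speech inhalation + exhalation)
      schedule_interjection(nxt, nxt_on, dI, cfg, quiet_fill, add_ts,
                            add_cycle, trough, rel_of)
      g2 <- rrange(cfg$interject_gap_s)
      resume_on <- nxt_on + dI + g2
      plant <- stats::runif(1) < cfg$hold_rates[[cat_minus]]
      sil0 <- e; sil1 <- resume_on
      sg <- if (plant) hold_segs(spk, sil0, sil1, cfg$silence_weight)
            else data.frame(t0 = sil0, t1 = sil1, w = cfg$silence_weight,
                            hold = FALSE)
      segs <- rbind(segs, sg)
      dR <- stats::runif(1, 1.2, 2.5)
      add_ts(spk, resume_on, resume_on + dR)
      segs <- rbind(segs, data.frame(t0 = resume_on, t1 = resume_on + dR,
                                     w = 1, hold = FALSE))
      hosts_minus <- TRUE
      e <- resume_on + dR
      # close spk's exhalation after the resumption
      tail <- rrange(cfg$tail_plus_s)
      segs <- rbind(segs, data.frame(t0 = e, t1 = e + tail,
                                     w = cfg$silence_weight, hold = FALSE))
      v_off <- min(rpar(cfg$minus_offset) + rel_of[[spk]], v_pk - 0.30)
      bp <- close_exhalation(spk, t_exh_start, v_pk, segs, v_off)
      emit_speech_cycle(spk, t_inh_on, v_on, t_exh_start, v_pk, bp, segs,
                        add_cycle, add_hold)
      prev_end[[spk]] <- e + tail
      prev_val[[spk]] <- v_off
      # floor moves on after the resumption with a plain silence change
      nxt2 <- sample(setdiff(speakers, spk), 1L)
      t_now <- e + rnormt(1, cfg$gap_bss_s[1], cfg$gap_bss_s[2],
                          cfg$gap_bss_s[3], cfg$gap_bss_s[4])
      spk <- nxt2
    } else {
      # ordinary +INH-side turn end; holds only on exhalations without a
      # -INH continuation (rate doubled to keep the realised per-category
      # co-occurrence near the configured value)
      plant <- !hosts_minus && stats::runif(1) < 2 * cfg$hold_rates[[cat_plus]]
      tail <- if (plant) rrange(cfg$tail_plus_hold_s) else rrange(cfg$tail_plus_s)
      sg <- if (plant) hold_segs(spk, e, e + tail, cfg$silence_weight)
            else data.frame(t0 = e, t1 = e + tail, w = cfg$silence_weight,
                            hold = FALSE)
      segs <- rbind(segs, sg)
      v_off <- if (hosts_minus) {
        min(rpar(cfg$minus_offset) + rel_of[[spk]], v_pk - 0.30)
      } else rel_of[[spk]] + stats::runif(1, 0, cfg$plus_offset_max)
      bp <- close_exhalation(spk, t_exh_start, v_pk, segs, v_off)
      emit_speech_cycle(spk, t_inh_on, v_on, t_exh_start, v_pk, bp, segs,
                        add_cycle, add_hold)
      prev_end[[spk]] <- e + tail
      prev_val[[spk]] <- v_off
      t_now <- nxt_on
      spk <- nxt
    }
  }

  # fill everyone out to the end of the conversation
  for (sp in speakers) {
    prev_val[[sp]] <- quiet_fill(sp, prev_end[[sp]], cfg$duration_s,
                                 prev_val[[sp]], trough(sp))
    prev_end[[sp]] <- cfg$duration_s
  }

  assemble_sim(cfg, speakers, cycles, talkspurts, laughter, holds_gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one speech cycle: splits hold segments out of the exhalation breakpoint
# path and records planted holds
emit_speech_cycle <- function(sp, t_inh_on, v_on, t_exh_start, v_pk, bp,
                              segs, add_cycle, add_hold) {
  add_cycle(sp, t_inh_on, v_on, t_exh_start, v_pk, bp)
  if (any(segs$hold)) {
    hs <- segs[segs$hold, , drop = FALSE]
    for (i in seq_len(nrow(hs))) {
      lvl <- stats::approx(bp$t, bp$v, xout = hs$t0[i], rule = 2)$y
      add_hold(sp, hs$t0[i], hs$t1[i], lvl, top = NA)
    }
  }
}

# interjector mini-episode: quiet fill to a pre-speech inhalation, one
# talkspurt on one exhalation, trough near REL
schedule_interjection <- function(sp, on, dI, cfg, quiet_fill, add_ts,
                                  add_cycle, trough, rel_of) {
  d_inh <- rnormt(1, cfg$inh_init_s[1], cfg$inh_init_s[2],
                  cfg$inh_init_s[3], cfg$inh_init_s[4])
  lag <- stats::runif(1, cfg$lag_init_s[1], cfg$lag_init_s[2])
  t_inh_on <- on - lag - d_inh
  env <- parent.frame()
  if (t_inh_on < env$prev_end[[sp]] + 1.2) {
    t_inh_on <- env$prev_end[[sp]]
    v_on <- env$prev_val[[sp]]
  } else {
    v_on <- trough(sp)
    env$prev_val[[sp]] <- quiet_fill(sp, env$prev_end[[sp]], t_inh_on,
                                     env$prev_val[[sp]], v_on)
  }
  v_pk <- max(rnormt(1, cfg$speech_peak[1], cfg$speech_peak[2],
                     cfg$speech_peak[3], cfg$speech_peak[4]), v_on + 0.30)
  t_exh_start <- on - lag
  if (t_exh_start <= t_inh_on + 0.2) t_exh_start <- t_inh_on + 0.2
  add_ts(sp, on, on + dI)
  tail <- stats::runif(1, cfg$tail_plus_s[1], cfg$tail_plus_s[2])
  v_off <- rel_of[[sp]] + stats::runif(1, 0, cfg$plus_offset_max)
  t_end <- on + dI + tail
  w <- c(cfg$pause_weight, 1, cfg$silence_weight)
  dur <- c(on - t_exh_start, dI, tail)
  drops <- (v_pk - v_off) * w * dur / sum(w * dur)
  bp <- data.frame(t = c(t_exh_start, on, on + dI, t_end),
                   v = c(v_pk, v_pk - drops[1], v_pk - drops[1] - drops[2],
                         v_off))
  bp <- bp[!duplicated(bp$t), , drop = FALSE]
  add_cycle(sp, t_inh_on, v_on, t_exh_start, v_pk, bp)
  env$prev_end[[sp]] <- t_end
  env$prev_val[[sp]] <- v_off
}

# render traces and derive ground-truth tables
assemble_sim <- function(cfg, speakers, cycles, talkspurts, laughter,
                         holds_gt) {
  ts <- do.call(rbind, talkspurts)
  ts <- ts[order(ts$t_start), , drop = FALSE]
  rownames(ts) <- NULL
  la <- if (length(laughter)) do.call(rbind, laughter) else
    data.frame(speaker = character(), t_start = numeric(), t_end = numeric(),
               stringsAsFactors = FALSE)
  hg <- if (length(holds_gt)) do.call(rbind, holds_gt) else
    data.frame(speaker = character(), t_start = numeric(), t_end = numeric(),
               level = numeric(), top = logical(), stringsAsFactors = FALSE)

  cyc_df <- do.call(rbind, lapply(cycles, function(cy) {
    data.frame(speaker = cy$speaker, t_onset = cy$t_onset,
               t_peak = cy$t_peak, t_offset = cy$exh$t[nrow(cy$exh)],
               v_onset = cy$v_onset, v_peak = cy$v_peak,
               v_offset = cy$exh$v[nrow(cy$exh)], stringsAsFactors = FALSE)
  }))
  cyc_df <- cyc_df[order(cyc_df$speaker, cyc_df$t_onset), , drop = FALSE]
  cyc_df <- do.call(rbind, lapply(split(cyc_df, cyc_df$speaker), function(d) {
    cbind(speaker = d$speaker, cycle = seq_len(nrow(d)),
          d[, -1, drop = FALSE], silent = NA)
  }))
  rownames(cyc_df) <- NULL
  cyc_df <- mark_silent_cycles_all(cyc_df, ts)

  # attach planted holds to their cycles
  if (nrow(hg) > 0L) {
    hg$cycle <- NA_integer_
    for (i in seq_len(nrow(hg))) {
      d <- cyc_df[cyc_df$speaker == hg$speaker[i], , drop = FALSE]
      j <- which(d$t_onset <= hg$t_start[i] & hg$t_start[i] < d$t_offset)
      if (length(j)) hg$cycle[i] <- d$cycle[j[1L]]
    }
  }

  # render one trace per speaker
  fs <- cfg$sample_rate_hz
  grid <- seq(0, cfg$duration_s, by = 1 / fs)
  traces <- lapply(speakers, function(sp) {
    cyl <- Filter(function(cy) cy$speaker == sp, cycles)
    cyl <- cyl[order(vapply(cyl, function(cy) cy$t_onset, numeric(1)))]
    bp_t <- numeric(); bp_v <- numeric()
    for (cy in cyl) {
      bp_t <- c(bp_t, cy$t_onset, cy$exh$t)
      bp_v <- c(bp_v, cy$v_onset, cy$exh$v)
    }
    # lead-in/out so that the first/last troughs are genuine extrema
    if (bp_t[1] > 0) { bp_t <- c(0, bp_t); bp_v <- c(bp_v[1] + 0.25, bp_v) }
    nb <- length(bp_t)
    if (bp_t[nb] < cfg$duration_s) {
      bp_t <- c(bp_t, cfg$duration_s); bp_v <- c(bp_v, bp_v[nb] + 0.25)
    }
    keep <- !duplicated(bp_t)
    y <- stats::approx(bp_t[keep], bp_v[keep], xout = grid, rule = 2)$y
    w <- max(1L, round(cfg$smooth_s * fs))
    y <- hann_smooth(y, w)
    amp <- mean(with(cyc_df[cyc_df$speaker == sp, ],
                     v_peak - pmin(v_onset, v_offset)))
    y <- y + stats::rnorm(length(y), 0, cfg$noise_sd * amp)
    rip_trace(y, fs, sp, "raw")
  })
  names(traces) <- speakers

  # ground-truth labels, derived from the planted landmarks
  mts <- merge_talkspurts(ts)
  mts <- flag_laughter(mts, la)
  ev <- classify_intervals(mts)
  ev <- augment_inh(ev, cyc_df, mts)
  ev <- apply_exclusions(ev, mts, cyc_df, la)
  tt <- tt_events(mts, cyc_df)
  hp <- if (nrow(hg) > 0L) hold_position(hg, cyc_df) else hg
  silent_key <- paste(cyc_df$speaker, cyc_df$cycle)[which(cyc_df$silent)]
  abandoned <- hp[paste(hp$speaker, hp$cycle) %in% silent_key &
                    !is.na(hp$rel_amp_pos) & hp$rel_amp_pos <= 0.2, ,
                  drop = FALSE]

  structure(list(
    traces = traces,
    intervals = ts,
    laughter = la,
    ground_truth = list(cycles = cyc_df, holds = hg, talkspurts = mts,
                        events = ev, tt = tt, abandoned = abandoned),
    config = cfg), class = "breathturn_sim")
}

hann_smooth <- function(x, w) {
  if (w <= 2L) return(x)
  k <- 0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1L))
  k <- k / sum(k)
  half <- (w - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], w - 1L - half))
  as.numeric(stats::filter(xp, k, sides = 1))[w:(w + length(x) - 1L)]
}

# silent flags for a multi-speaker cycle table
mark_silent_cycles_all <- function(cycles, talkspurts) {
  out <- lapply(split(cycles, cycles$speaker), mark_silent_cycles,
                talkspurts = talkspurts)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$speaker, out$cycle), , drop = FALSE]
}

#' @export
print.breathturn_sim <- function(x, ...) {
  cat(sprintf(
    "<breathturn_sim> %d speakers, %.0f s, %d talkspurts, %d cycles, %d planted holds\n",
    length(x$traces), x$config$duration_s, nrow(x$intervals),
    nrow(x$ground_truth$cycles), nrow(x$ground_truth$holds)))
  invisible(x)
}
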