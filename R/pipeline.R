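#' Full analysis pipeline
#'
#' `analyze_conversation()` runs every stage in memory: per-speaker
#' normalisation (resampling, z-scoring), cycle segmentation, SV/REL
#' calibration, hold detection restricted to silent exhalations,
#' chronogram classification with the inhalation augmentation and
#' exclusion filters, kinematic feature extraction with the extreme-slope
#' filter, hidden-event analysis and (optionally) the four multinomial
#' model families. [run_pipeline()] wraps it with file input/output and a
#' run manifest.
#'
#' @name io_cli
NULL

#' Default pipeline configuration
#'
#' All tunable parameters of the analysis stages with their defaults;
#' any subset can be overridden. The same keys are understood by the
#' YAML configuration file (see [read_config()]).
#'
#' @param ... overrides, e.g. `default_config(rel_window_s = 30)`.
#' @return a named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    working_rate_hz = 100,   # uniform resampling rate before segmentation
    min_sep_sd = 1.0,        # peak-trough separation, z units
    segment_smooth_ms = 100, # moving average before landmark search
    refine_landmarks = TRUE, # median-filter refinement of landmark times
    rel_window_s = 60,       # REL median window
    rel_align = "centred",
    quantile_type = 7,       # SV percentile convention
    min_hold_s = 0.25,
    min_gap_s = 0.15,
    margin_frac = 0.025,
    n_bins = 100,
    prominence_ratio = 3,
    smooth_ms = 100,
    min_pause_s = 0.2,
    backchannel_s = 1.0,
    top_amp_frac = 0.2,
    slope_sd_k = 3,
    slope_denominator = "duration",
    alpha = 0.05,
    fit_models = TRUE,
    stepwise = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  cfg
}

#' Run the full analysis on in-memory inputs
#'
#' @param traces named list of raw [rip_trace()]s, one per speaker.
#' @param intervals raw speech-activity intervals (`speaker`, `t_start`,
#'   `t_end`).
#' @param laughter optional laughter intervals (same columns).
#' @param config a [default_config()] list.
#' @return a list with `cycles` (SV units, silent flags), `calibrations`,
#'   `holds` (silent-exhalation holds), `talkspurts`, `events`, `tt`,
#'   `features` (after the extreme-slope filter), `candidates`
#'   (abandoned initiations), `hold_condition`, `silent_groups` and
#'   `models` (NULL unless `config$fit_models`; families that lack data
#'   are recorded as `NA` with the error message).
#' @export
analyze_conversation <- function(traces, intervals, laughter = NULL,
                                 config = default_config()) {
  stopifnot(is.list(traces), length(traces) > 0)
  # --- segment + calibrate each speaker -------------------------------
  cycles <- list(); calibs <- list(); sv_traces <- list()
  for (sp in names(traces)) {
    tr <- resample_trace(traces[[sp]], config$working_rate_hz)
    trz <- zscore_trace(tr)
    seg_in <- trz
    if (config$segment_smooth_ms > 0) {
      w <- max(1L, round(config$segment_smooth_ms / 1000 * trz$sample_rate))
      seg_in$samples <- moving_average(trz$samples, w)
    }
    cyc <- segment_cycles(seg_in, min_sep = config$min_sep_sd)
    if (isTRUE(config$refine_landmarks)) cyc <- refine_landmarks(cyc, seg_in)
    if (nrow(cyc) < 2L) {
      stop(sprintf("stage segment: fewer than 2 cycles for speaker %s", sp),
           call. = FALSE)
    }
    calib <- calibrate_speaker(cyc, window_s = config$rel_window_s,
                               align = config$rel_align,
                               type = config$quantile_type)
    sv_traces[[sp]] <- to_sv_units(trz, calib)
    cycles[[sp]] <- calibrate_cycles(cyc, calib)
    calibs[[sp]] <- calib
  }
  # --- talkspurts ------------------------------------------------------
  talkspurts <- merge_talkspurts(intervals, min_pause_s = config$min_pause_s,
                                 backchannel_s = config$backchannel_s)
  talkspurts <- flag_laughter(talkspurts, laughter)
  cycles <- lapply(cycles, mark_silent_cycles, talkspurts = talkspurts)
  cyc_all <- do.call(rbind, cycles)
  rownames(cyc_all) <- NULL
  # --- holds -----------------------------------------------------------
  holds <- do.call(rbind, lapply(names(sv_traces), function(sp) {
    detect_holds(sv_traces[[sp]], cycles[[sp]],
                 min_hold_s = config$min_hold_s,
                 min_gap_s = config$min_gap_s,
                 margin_frac = config$margin_frac,
                 n_bins = config$n_bins,
                 prominence_ratio = config$prominence_ratio,
                 smooth_ms = config$smooth_ms)
  }))
  holds <- filter_silent_holds(holds, talkspurts)
  # --- chronogram ------------------------------------------------------
  events <- classify_intervals(talkspurts)
  events <- augment_inh(events, cyc_all, talkspurts)
  events <- apply_exclusions(events, talkspurts, cyc_all, laughter)
  tt <- tt_events(talkspurts, cyc_all)
  # --- features --------------------------------------------------------
  floor_s <- 1 / config$working_rate_hz
  features <- feature_table(events, tt, cyc_all, talkspurts, holds,
                            slope_denominator = config$slope_denominator,
                            floor_s = floor_s)
  features <- flag_extreme_slopes(features, k = config$slope_sd_k)
  # --- hidden events ---------------------------------------------------
  candidates <- abandoned_candidates(cyc_all, holds,
                                     top_amp_frac = config$top_amp_frac)
  hold_condition <- speaker_change_given_hold(events, holds, cyc_all)
  silent_groups <- silent_cycle_groups(cyc_all, candidates, tt,
                                       floor_s = floor_s)
  # --- models ----------------------------------------------------------
  models <- NULL
  if (isTRUE(config$fit_models)) {
    models <- list()
    for (fam in c("exhalatory", "inhalatory_all", "inhalatory_tt")) {
      models[[fam]] <- tryCatch(
        fit_family(features, fam, stepwise = config$stepwise,
                   alpha = config$alpha),
        error = function(e) structure(list(error = conditionMessage(e)),
                                      class = "breathturn_fit_failure"))
    }
    models$silent_cycle <- tryCatch(
      fit_family(silent_groups, "silent_cycle", stepwise = config$stepwise,
                 alpha = config$alpha),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "breathturn_fit_failure"))
  }
  list(cycles = cyc_all, calibrations = calibs, holds = holds,
       talkspurts = talkspurts, events = events, tt = tt,
       features = features, candidates = candidates,
       hold_condition = hold_condition, silent_groups = silent_groups,
       models = models, config = config)
}

#' Conversation bundle
#'
#' Paths (or in-memory objects) tying one conversation's inputs together.
#'
#' @param conversation_id identifier used in the output files.
#' @param traces named list: per speaker either a [rip_trace()] or a path
#'   to a WAV / two-column delimited text file.
#' @param annotations speech-activity intervals: a data.frame, a TextGrid
#'   path (one interval tier per speaker) or a TSV path with columns
#'   `speaker`, `t_start`, `t_end`.
#' @param laughter optional laughter intervals in the same formats.
#' @param language optional language tag.
#' @return an object of class `conversation_bundle`.
#' @export
conversation_bundle <- function(conversation_id, traces, annotations,
                                laughter = NULL, language = NA_character_) {
  for (sp in names(traces)) {
    p <- traces[[sp]]
    if (is.character(p) && !file.exists(p)) {
      stop(sprintf("trace file for speaker %s not found: %s", sp, p),
           call. = FALSE)
    }
  }
  structure(list(conversation_id = conversation_id, traces = traces,
                 annotations = annotations, laughter = laughter,
                 language = language),
            class = "conversation_bundle")
}

load_bundle_traces <- function(bundle) {
  out <- list()
  for (sp in names(bundle$traces)) {
    p <- bundle$traces[[sp]]
    out[[sp]] <- if (inherits(p, "rip_trace")) p else read_trace(p, speaker_id = sp)
  }
  out
}

load_bundle_intervals <- function(x) {
  if (is.null(x) || is.data.frame(x)) return(x)
  if (grepl("\\.TextGrid$", x, ignore.case = TRUE)) {
    tg <- read_textgrid(x)
    return(textgrid_to_intervals(tg))
  }
  utils::read.delim(x, stringsAsFactors = FALSE)
}

#' Run the pipeline on a conversation bundle, writing per-stage files
#'
#' Runs segment, holds, chronogram, features, hidden and fit, writing one
#' TSV per stage, a JSON run manifest (package version, seed, config) and
#' a plain-text log with per-reason exclusion counts. Outputs are
#' deterministic: rerunning with the same inputs and configuration gives
#' byte-identical TSVs.
#'
#' @param bundle a [conversation_bundle()].
#' @param config a [default_config()] list.
#' @param out_dir output directory (created if needed).
#' @param seed optional seed recorded in the manifest (the analysis itself
#'   is deterministic; the seed matters only when the caller simulated the
#'   inputs).
#' @return the [analyze_conversation()] result, invisibly.
#' @export
run_pipeline <- function(bundle, config = default_config(), out_dir,
                         seed = NULL) {
  stopifnot(inherits(bundle, "conversation_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traces <- load_bundle_traces(bundle)
  intervals <- load_bundle_intervals(bundle$annotations)
  laughter <- load_bundle_intervals(bundle$laughter)
  res <- analyze_conversation(traces, intervals, laughter, config)
  id <- bundle$conversation_id
  wr <- function(d, name) {
    d2 <- cbind(conversation_id = id, d)
    write_tsv(d2, file.path(out_dir, paste0(name, ".tsv")))
  }
  wr(res$cycles, "cycles")
  wr(res$holds, "holds")
  ev <- res$events
  ev$category <- event_category(ev)
  wr(ev, "events")
  wr(res$tt, "tt_events")
  wr(res$features, "features")
  wr(res$candidates, "candidates")
  wr(res$silent_groups, "silent_groups")
  hc <- res$hold_condition
  wr(data.frame(n_silence_with_hold = hc$n_silence_with_hold,
                n_silence_without_hold = hc$n_silence_without_hold,
                n_change_with_hold = hc$n_change_with_hold,
                n_change_without_hold = hc$n_change_without_hold,
                p_change_given_hold = hc$p_change_given_hold,
                p_change_given_no_hold = hc$p_change_given_no_hold),
     "hold_condition")
  if (!is.null(res$models)) {
    tabs <- lapply(names(res$models), function(fam) {
      m <- res$models[[fam]]
      if (inherits(m, "breathturn_fit_failure")) return(NULL)
      cbind(family = fam, summary(m$fit)$table,
            mcfadden_r2 = m$fit$mcfadden_r2, n = m$n)
    })
    tabs <- tabs[!vapply(tabs, is.null, logical(1))]
    if (length(tabs)) wr(do.call(rbind, tabs), "models")
  }
  excl <- table(res$events$excluded, useNA = "no")
  manifest <- list(
    conversation_id = id,
    package = "breathturn",
    version = as.character(utils::packageVersion("breathturn")),
    seed = seed,
    stages = c("segment", "holds", "chronogram", "features", "hidden", "fit"),
    config = config,
    config_hash = config_hash(config),
    n_cycles = nrow(res$cycles), n_holds = nrow(res$holds),
    n_events = nrow(res$events), n_candidates = nrow(res$candidates),
    excluded = as.list(excl))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_lines <- c(
    sprintf("run_pipeline: conversation %s at %s", id, format(Sys.time())),
    sprintf("stages completed: %s", paste(manifest$stages, collapse = ", ")),
    sprintf("cycles %d, silent holds %d, events %d, abandoned candidates %d",
            nrow(res$cycles), nrow(res$holds), nrow(res$events),
            nrow(res$candidates)),
    sprintf("excluded events: %s",
            paste(sprintf("%s=%d", names(excl), excl), collapse = ", ")))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(res)
}

config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(x)
    paste(format(x, digits = 15), collapse = ","), character(1)),
    collapse = ";")
  # small rolling hash; enough to detect config changes in the manifest
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Compare pipeline output against simulation ground truth
#'
#' Per-stage recovery metrics on a simulated conversation: precision and
#' recall of cycle landmarks (within `tol_s`), of planted holds and of
#' abandoned candidates (temporal-overlap matching), agreement of the
#' inhalation augmentation and of the TT labels, the event-category
#' confusion matrix, and the largest absolute difference between
#' exhalatory-model coefficients fitted on ground-truth features versus
#' pipeline features.
#'
#' @param sim a [simulate_conversation()] result.
#' @param res an [analyze_conversation()] result on `sim`'s outputs.
#' @param tol_s landmark matching tolerance in seconds (default 0.1).
#' @param min_hold_s only planted holds at least this long enter the
#'   hold-recovery metric (default 0.3 s).
#' @return a list of metric blocks; `print()` gives a compact report.
#' @export
pipeline_recovery_report <- function(sim, res, tol_s = 0.1, min_hold_s = 0.3) {
  gt <- sim$ground_truth
  # --- cycle landmarks -------------------------------------------------
  cyc_pr <- lapply(split(gt$cycles, gt$cycles$speaker), function(g) {
    d <- res$cycles[res$cycles$speaker == g$speaker[1], , drop = FALSE]
    gt_lm <- sort(unique(c(g$t_onset, g$t_peak, g$t_offset)))
    det_lm <- sort(unique(c(d$t_onset, d$t_peak, d$t_offset)))
    rec <- mean(vapply(gt_lm, function(t0) any(abs(det_lm - t0) <= tol_s),
                       logical(1)))
    prec <- mean(vapply(det_lm, function(t0) any(abs(gt_lm - t0) <= tol_s),
                        logical(1)))
    c(precision = prec, recall = rec)
  })
  cycle_metrics <- colMeans(do.call(rbind, cyc_pr))
  # --- holds -----------------------------------------------------------
  hold_metrics <- overlap_prf(
    gt$holds[gt$holds$t_end - gt$holds$t_start >= min_hold_s, , drop = FALSE],
    res$holds)
  # --- abandoned candidates -------------------------------------------
  cand_metrics <- overlap_prf(gt$abandoned, res$candidates)
  # --- event labels ----------------------------------------------------
  key <- function(e) sprintf("%s|%s|%.3f", e$base, e$prev_speaker, e$t_start)
  ge <- gt$events; de <- res$events
  m <- match(key(ge), key(de))
  matched <- !is.na(m)
  inh_sel <- matched & ge$base %in% c("WSS", "BSS", "BSO")
  inh_agreement <- mean(ge$inh[inh_sel] == de$inh[m[inh_sel]])
  confusion <- table(truth = event_category(ge)[matched],
                     detected = event_category(de)[m[matched]])
  tt_key <- function(x) sprintf("%s|%.3f", x$speaker, x$t_start)
  mt <- match(tt_key(gt$tt), tt_key(res$tt))
  tt_agreement <- mean(gt$tt$kind == res$tt$kind[mt], na.rm = FALSE)
  # --- coefficient recovery -------------------------------------------
  coef_err <- tryCatch({
    # ground-truth cycles are in raw trace units: z-score them with the
    # trace moments, then apply the pipeline's own calibration
    gcyc <- do.call(rbind, lapply(split(gt$cycles, gt$cycles$speaker),
      function(d) {
        sp <- d$speaker[1]
        x <- sim$traces[[sp]]$samples
        for (col in c("v_onset", "v_peak", "v_offset")) {
          d[[col]] <- (d[[col]] - mean(x)) / stats::sd(x)
        }
        calibrate_cycles(d, res$calibrations[[sp]])
      }))
    rownames(gcyc) <- NULL
    gfeat <- feature_table(ge, gt$tt, gcyc, gt$talkspurts, res$holds)
    f_gt <- fit_family(gfeat, "exhalatory", stepwise = FALSE)
    f_pl <- fit_family(res$features, "exhalatory", stepwise = FALSE)
    max(abs(coef(f_gt$fit) - coef(f_pl$fit)))
  }, error = function(e) NA_real_)
  structure(list(cycles = cycle_metrics, holds = hold_metrics,
                 candidates = cand_metrics,
                 inh_agreement = inh_agreement,
                 tt_agreement = tt_agreement,
                 confusion = confusion,
                 event_match_rate = mean(matched),
                 exh_coef_max_abs_diff = coef_err),
            class = "recovery_report")
}

# precision/recall/F1 by temporal overlap >= half the shorter interval
overlap_prf <- function(truth, det) {
  if (nrow(truth) == 0L) {
    return(c(precision = NA_real_, recall = NA_real_, f1 = NA_real_,
             n_truth = 0, n_detected = nrow(det)))
  }
  match_one <- function(a, b) {
    ov <- pmin(a[["t_end"]], b$t_end) - pmax(a[["t_start"]], b$t_start)
    len <- pmin(a[["t_end"]] - a[["t_start"]], b$t_end - b$t_start)
    any(b$speaker == a[["speaker"]] & ov >= 0.5 * len)
  }
  rec <- vapply(seq_len(nrow(truth)), function(i)
    nrow(det) > 0 && match_one(truth[i, ], det), logical(1))
  prec <- if (nrow(det) == 0L) NA_real_ else
    mean(vapply(seq_len(nrow(det)), function(i)
      match_one(det[i, ], truth), logical(1)))
  r <- mean(rec)
  f1 <- if (is.na(prec) || prec + r == 0) NA_real_ else
    2 * prec * r / (prec + r)
  c(precision = prec, recall = r, f1 = f1,
    n_truth = nrow(truth), n_detected = nrow(det))
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Pipeline recovery against simulation ground truth\n")
  cat(sprintf("  cycle landmarks: precision %.3f, recall %.3f\n",
              x$cycles[["precision"]], x$cycles[["recall"]]))
  cat(sprintf("  holds (>= min duration): P %.3f, R %.3f, F1 %.3f (%d planted, %d detected)\n",
              x$holds[["precision"]], x$holds[["recall"]], x$holds[["f1"]],
              x$holds[["n_truth"]], x$holds[["n_detected"]]))
  cat(sprintf("  abandoned candidates: P %.3f, R %.3f (%d planted)\n",
              x$candidates[["precision"]], x$candidates[["recall"]],
              x$candidates[["n_truth"]]))
  cat(sprintf("  +/-INH agreement %.3f, TT label agreement %.3f, events matched %.3f\n",
              x$inh_agreement, x$tt_agreement, x$event_match_rate))
  cat(sprintf("  exhalatory-model max |coef diff| %.3g\n",
              x$exh_coef_max_abs_diff))
  invisible(x)
}
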