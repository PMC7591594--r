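#' Aggregate several analysed conversations
#'
#' Pools the per-conversation outputs of [analyze_conversation()] into
#' corpus-level quantities: the hold-conditioned speaker-change
#' probabilities (counts summed before dividing), the abandoned-candidate
#' versus hold-free silent-cycle split, per-category hold co-occurrence
#' rates, and the four multinomial model families refitted on the pooled
#' feature tables.
#'
#' @param results list of [analyze_conversation()] results.
#' @param stepwise use stepwise selection in the pooled fits.
#' @param alpha stepwise significance level.
#' @return a list with `hold_condition` (pooled counts and
#'   probabilities), `n_abandoned`, `n_silent_without_hold`,
#'   `hold_cooccurrence` (per-category percentage of non-excluded events
#'   whose anchoring exhalation carries a hold), `models` (pooled fits or
#'   fit-failure records) and `n_conversations`.
#' @export
aggregate_analyses <- function(results, stepwise = TRUE, alpha = 0.05) {
  stopifnot(length(results) > 0)
  counts <- c(n_silence_with_hold = 0, n_silence_without_hold = 0,
              n_change_with_hold = 0, n_change_without_hold = 0)
  feats <- list(); groups <- list()
  n_abandoned <- 0L; n_silent_no_hold <- 0L
  for (i in seq_along(results)) {
    r <- results[[i]]
    hc <- r$hold_condition
    counts <- counts + c(hc$n_silence_with_hold, hc$n_silence_without_hold,
                         hc$n_change_with_hold, hc$n_change_without_hold)
    f <- r$features; f$conversation <- i
    feats[[i]] <- f
    g <- r$silent_groups; g$conversation <- i
    groups[[i]] <- g
    n_abandoned <- n_abandoned + nrow(r$candidates)
    n_silent_no_hold <- n_silent_no_hold + sum(r$silent_groups$group == "Silent")
  }
  features <- do.call(rbind, feats)
  silent_groups <- do.call(rbind, groups)
  hc <- list(
    n_silence_with_hold = counts[[1]], n_silence_without_hold = counts[[2]],
    n_change_with_hold = counts[[3]], n_change_without_hold = counts[[4]],
    p_change_given_hold = if (counts[[1]] > 0) counts[[3]] / counts[[1]] else NA_real_,
    p_change_given_no_hold = if (counts[[2]] > 0) counts[[4]] / counts[[2]] else NA_real_)
  class(hc) <- "hold_condition_table"
  ok <- is.na(features$excluded) & !is.na(features$hold_present)
  cooc <- tapply(features$hold_present[ok], features$category[ok],
                 function(x) 100 * mean(x))
  models <- list()
  for (fam in c("exhalatory", "inhalatory_all", "inhalatory_tt")) {
    models[[fam]] <- tryCatch(
      fit_family(features, fam, stepwise = stepwise, alpha = alpha),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "breathturn_fit_failure"))
  }
  models$silent_cycle <- tryCatch(
    fit_family(silent_groups, "silent_cycle", stepwise = stepwise,
               alpha = alpha),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "breathturn_fit_failure"))
  list(hold_condition = hc, n_abandoned = n_abandoned,
       n_silent_without_hold = n_silent_no_hold,
       hold_cooccurrence = cooc, models = models,
       features = features, silent_groups = silent_groups,
       n_conversations = length(results))
}

#' Analyse a downloaded corpus directory
#'
#' Runs the full pipeline over a local copy of a recorded corpus and
#' aggregates the results. The expected layout is one subdirectory per
#' conversation containing one mono WAV (or two-column text) lung-volume
#' trace per speaker, a `speech.TextGrid` (or any `*.TextGrid`) with one
#' interval tier per speaker, and optionally a `laughter.tsv`
#' (`speaker`, `t_start`, `t_end`). Adapt the files to this layout when
#' an archive uses a different one.
#'
#' @param dir corpus root directory.
#' @param config pipeline configuration.
#' @return the [aggregate_analyses()] summary.
#' @export
reproduce_corpus <- function(dir, config = default_config()) {
  if (!dir.exists(dir)) {
    stop(sprintf("corpus directory not found: %s", dir), call. = FALSE)
  }
  convs <- list.dirs(dir, recursive = FALSE)
  if (length(convs) == 0L) {
    stop(sprintf("no conversation subdirectories under %s", dir), call. = FALSE)
  }
  results <- lapply(convs, function(cd) {
    wavs <- list.files(cd, pattern = "\\.(wav|txt|tsv)$", full.names = TRUE,
                       ignore.case = TRUE)
    wavs <- wavs[!grepl("laughter", basename(wavs))]
    if (length(wavs) == 0L) {
      stop(sprintf("no trace files in %s", cd), call. = FALSE)
    }
    traces <- list()
    for (p in wavs) {
      sp <- sub("\\.[^.]+$", "", basename(p))
      traces[[sp]] <- read_trace(p, speaker_id = sp)
    }
    tg <- list.files(cd, pattern = "\\.TextGrid$", full.names = TRUE)
    if (length(tg) == 0L) {
      stop(sprintf("no TextGrid in %s", cd), call. = FALSE)
    }
    intervals <- textgrid_to_intervals(read_textgrid(tg[1L]))
    lp <- file.path(cd, "laughter.tsv")
    laughter <- if (file.exists(lp)) read_tsv(lp) else NULL
    analyze_conversation(traces, intervals, laughter, config)
  })
  aggregate_analyses(results)
}
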