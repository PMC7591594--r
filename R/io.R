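#' Interchange-format helpers
#'
#' TSVs carry a header row, UTF-8 text and times serialised as seconds
#' with six decimals; writers and readers round-trip losslessly for the
#' tables the pipeline produces.
#'
#' @param d data.frame to write.
#' @param path file path.
#' @export
write_tsv <- function(d, path) {
  d2 <- d
  for (col in names(d2)) {
    if (is.numeric(d2[[col]]) && !is.integer(d2[[col]])) {
      d2[[col]] <- formatC(d2[[col]], format = "f", digits = 6)
      d2[[col]][d2[[col]] %in% c("NA", "NaN")] <- NA
    }
  }
  utils::write.table(d2, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read a lung-volume trace from WAV or delimited text
#'
#' WAV files provide the sample rate in the header. Delimited text must
#' have two columns (time in seconds, value); the sample rate is inferred
#' from the median time step and the series is required to be uniform to
#' within 1%.
#'
#' @param path input file (`.wav` or delimited text).
#' @param speaker_id speaker identifier for the resulting trace.
#' @return a raw [rip_trace()].
#' @export
read_trace <- function(path, speaker_id = "spk") {
  if (grepl("\\.wav$", path, ignore.case = TRUE)) {
    w <- read_wav(path)
    return(rip_trace(w$samples, w$sample_rate, speaker_id, "raw"))
  }
  d <- utils::read.table(path, header = FALSE, sep = "",
                         col.names = c("time_s", "value"),
                         colClasses = "numeric", comment.char = "#",
                         skip = has_header(path))
  dt <- diff(d$time_s)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 0.01 * stats::median(dt)) {
    stop("trace text file must be uniformly sampled with increasing times",
         call. = FALSE)
  }
  rip_trace(d$value, 1 / stats::median(dt), speaker_id, "raw",
            t0 = d$time_s[1])
}

has_header <- function(path) {
  first <- readLines(path, n = 1L)
  as.integer(is.na(suppressWarnings(as.numeric(strsplit(trimws(first),
                                                        "\\s+")[[1]][1]))))
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults. A
#' full-default template ships with the package:
#' `system.file("extdata", "default_config.yaml", package = "breathturn")`.
#'
#' @param path YAML file with [default_config()] keys.
#' @return a config list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

#' Write simulated conversations in the pipeline's interchange formats
#'
#' Emits one WAV trace per speaker, a speech-activity TextGrid (one tier
#' per speaker) plus laughter TSV, and the ground-truth tables as TSVs.
#'
#' @param sim a [simulate_conversation()] result.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$traces)) {
    tr <- sim$traces[[sp]]
    write_wav(tr$samples / max(abs(tr$samples)), tr$sample_rate,
              file.path(dir, paste0(sp, ".wav")))
  }
  tiers <- lapply(split(sim$intervals, sim$intervals$speaker), function(d) {
    data.frame(t_start = d$t_start, t_end = d$t_end, label = "speech",
               stringsAsFactors = FALSE)
  })
  write_textgrid(tiers, file.path(dir, "speech.TextGrid"),
                 xmax = sim$config$duration_s)
  write_tsv(sim$laughter, file.path(dir, "laughter.tsv"))
  gt <- sim$ground_truth
  write_tsv(gt$cycles, file.path(dir, "gt_cycles.tsv"))
  write_tsv(gt$holds, file.path(dir, "gt_holds.tsv"))
  ev <- gt$events
  ev$category <- event_category(ev)
  write_tsv(ev, file.path(dir, "gt_events.tsv"))
  write_tsv(gt$tt, file.path(dir, "gt_tt.tsv"))
  invisible(dir)
}
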