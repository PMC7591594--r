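#' Praat TextGrid reading and writing
#'
#' Reads both TextGrid dialects (the verbose "long" format and the
#' compact "short" format), keeping interval tiers only. Empty-label
#' intervals are retained; point tiers are skipped. The writer emits the
#' long dialect.
#'
#' @param path path to a TextGrid file (UTF-8 or ASCII).
#' @return a named list of data.frames (one per interval tier) with
#'   columns `t_start`, `t_end`, `label`.
#' @export
read_textgrid <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!any(grepl("ooTextFile", lines[seq_len(min(3, length(lines)))]))) {
    stop(sprintf("parse error at line 1: %s is not a Praat TextGrid", path),
         call. = FALSE)
  }
  if (any(grepl("item\\s*\\[", lines))) {
    parse_textgrid_long(lines, path)
  } else {
    parse_textgrid_short(lines, path)
  }
}

tg_num <- function(line) as.numeric(sub(".*=\\s*", "", line))
tg_str <- function(line) {
  m <- regmatches(line, regexpr('"(\\\\.|[^"]|"")*"', line))
  if (length(m) == 0L) return("")
  gsub('""', '"', substr(m, 2, nchar(m) - 1L))
}

parse_textgrid_long <- function(lines, path) {
  tiers <- list()
  i <- 1L; n <- length(lines)
  cur_name <- NULL; cur <- NULL; is_interval <- FALSE
  flush <- function() {
    if (!is.null(cur_name) && is_interval) {
      tiers[[cur_name]] <<- if (length(cur)) {
        do.call(rbind, cur)
      } else {
        data.frame(t_start = numeric(), t_end = numeric(),
                   label = character(), stringsAsFactors = FALSE)
      }
    }
  }
  while (i <= n) {
    ln <- lines[i]
    if (grepl("class\\s*=", ln)) {
      flush()
      is_interval <- grepl("IntervalTier", ln)
      cur <- list(); cur_name <- NULL
    } else if (grepl("^\\s*name\\s*=", ln)) {
      cur_name <- tg_str(ln)
      if (!nzchar(cur_name)) cur_name <- sprintf("tier%d", length(tiers) + 1L)
    } else if (is_interval && grepl("intervals\\s*\\[", ln)) {
      if (i + 3L > n) {
        stop(sprintf("parse error at line %d: truncated interval", i),
             call. = FALSE)
      }
      xmin <- tg_num(lines[i + 1L]); xmax <- tg_num(lines[i + 2L])
      lab <- tg_str(lines[i + 3L])
      if (!is.finite(xmin) || !is.finite(xmax)) {
        stop(sprintf("parse error at line %d: bad interval bounds", i + 1L),
             call. = FALSE)
      }
      cur[[length(cur) + 1L]] <- data.frame(
        t_start = xmin, t_end = xmax, label = lab, stringsAsFactors = FALSE)
      i <- i + 3L
    }
    i <- i + 1L
  }
  flush()
  tiers
}

parse_textgrid_short <- function(lines, path) {
  # strip header: ooTextFile line, "TextGrid", xmin, xmax, <exists>, ntiers
  toks <- lines[nzchar(trimws(lines))]
  body <- toks[-seq_len(2L)]   # drop the two ooTextFile header lines
  # body: xmin xmax <exists> ntiers then per tier:
  #   "IntervalTier" "name" xmin xmax n  then n * (xmin xmax "label")
  p <- 1L
  num <- function() { v <- as.numeric(body[p]); p <<- p + 1L; v }
  str <- function() { v <- tg_str(body[p]); p <<- p + 1L; v }
  num(); num()
  exists_flag <- body[p]; p <- p + 1L
  ntier <- num()
  if (!is.finite(ntier)) {
    stop("parse error: malformed short TextGrid header", call. = FALSE)
  }
  tiers <- list()
  for (k in seq_len(ntier)) {
    cls <- str(); nm <- str()
    if (!nzchar(nm)) nm <- sprintf("tier%d", k)
    num(); num()
    ni <- num()
    if (!is.finite(ni)) {
      stop(sprintf("parse error near token %d: bad interval count", p),
           call. = FALSE)
    }
    if (grepl("IntervalTier", cls)) {
      rows <- vector("list", ni)
      for (j in seq_len(ni)) {
        xmin <- num(); xmax <- num(); lab <- str()
        rows[[j]] <- data.frame(t_start = xmin, t_end = xmax, label = lab,
                                stringsAsFactors = FALSE)
      }
      tiers[[nm]] <- if (ni) do.call(rbind, rows) else
        data.frame(t_start = numeric(), t_end = numeric(),
                   label = character(), stringsAsFactors = FALSE)
    } else {
      for (j in seq_len(ni)) { num(); str() }   # skip point tier
    }
  }
  tiers
}

#' @rdname read_textgrid
#' @param tiers named list of interval data.frames (`t_start`, `t_end`,
#'   `label`); gaps are filled with empty-label intervals on writing.
#' @param xmax total duration; defaults to the latest interval end.
#' @export
write_textgrid <- function(tiers, path, xmax = NULL) {
  if (is.null(xmax)) {
    xmax <- max(vapply(tiers, function(d)
      if (nrow(d)) max(d$t_end) else 0, numeric(1)))
  }
  esc <- function(s) gsub('"', '""', s)
  out <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
           "xmin = 0 ", sprintf("xmax = %.6f ", xmax),
           "tiers? <exists> ", sprintf("size = %d ", length(tiers)),
           "item []: ")
  for (k in seq_along(tiers)) {
    d <- tiers[[k]][order(tiers[[k]]$t_start), , drop = FALSE]
    # pad gaps with empty intervals so that the tier tiles [0, xmax]
    full <- list(); t0 <- 0
    for (i in seq_len(nrow(d))) {
      if (d$t_start[i] > t0 + 1e-9) {
        full[[length(full) + 1L]] <- data.frame(t_start = t0,
                                                t_end = d$t_start[i],
                                                label = "")
      }
      full[[length(full) + 1L]] <- d[i, c("t_start", "t_end", "label")]
      t0 <- d$t_end[i]
    }
    if (t0 < xmax - 1e-9) {
      full[[length(full) + 1L]] <- data.frame(t_start = t0, t_end = xmax,
                                              label = "")
    }
    full <- if (length(full)) do.call(rbind, full) else
      data.frame(t_start = 0, t_end = xmax, label = "")
    out <- c(out,
             sprintf("    item [%d]:", k),
             '        class = "IntervalTier" ',
             sprintf('        name = "%s" ', esc(names(tiers)[k])),
             "        xmin = 0 ",
             sprintf("        xmax = %.6f ", xmax),
             sprintf("        intervals: size = %d ", nrow(full)))
    for (i in seq_len(nrow(full))) {
      out <- c(out,
               sprintf("        intervals [%d]:", i),
               sprintf("            xmin = %.6f ", full$t_start[i]),
               sprintf("            xmax = %.6f ", full$t_end[i]),
               sprintf('            text = "%s" ', esc(full$label[i])))
    }
  }
  writeLines(out, path, useBytes = FALSE)
  invisible(path)
}

#' Flatten a TextGrid tier list into a speech-activity interval table
#'
#' Non-empty labels count as speech; the tier name is the speaker id.
#'
#' @param tiers result of [read_textgrid()].
#' @return data.frame with `speaker`, `t_start`, `t_end`, `label`.
#' @export
textgrid_to_intervals <- function(tiers) {
  rows <- lapply(names(tiers), function(nm) {
    d <- tiers[[nm]]
    d <- d[nzchar(trimws(d$label)), , drop = FALSE]
    if (!nrow(d)) return(NULL)
    data.frame(speaker = nm, t_start = d$t_start, t_end = d$t_end,
               label = d$label, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(speaker = character(), t_start = numeric(),
                      t_end = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$t_start), , drop = FALSE]
}
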