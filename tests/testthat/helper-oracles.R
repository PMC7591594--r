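# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use different algorithms (O(n^2)
# loops, discretised sweeps) from the production code paths.

# two-pass mean/SD by plain summation
oracle_moments <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s2 <- sum((x - m)^2) / (n - 1)
  c(mean = m, sd = sqrt(s2))
}

# exhaustive local-extremum scan (loop over samples, flats -> first
# sample) followed by greedy prominence pruning: repeatedly drop the
# adjacent landmark pair with the smallest value difference until every
# adjacent pair differs by at least min_sep, re-enforcing alternation
# after every removal
oracle_landmarks <- function(x, min_sep) {
  n <- length(x)
  idx <- integer(); val <- numeric(); typ <- character()
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    if (j <= n - 1L) {
      if (x[i - 1L] < x[i] && x[j + 1L] < x[i]) {
        idx <- c(idx, i); val <- c(val, x[i]); typ <- c(typ, "max")
      } else if (x[i - 1L] > x[i] && x[j + 1L] > x[i]) {
        idx <- c(idx, i); val <- c(val, x[i]); typ <- c(typ, "min")
      }
    }
    i <- j + 1L
  }
  fix_alt <- function(idx, val, typ) {
    repeat {
      if (length(idx) < 2L) break
      same <- which(typ[-length(typ)] == typ[-1L])
      if (!length(same)) break
      k <- same[1L]
      drop <- if (typ[k] == "max") {
        if (val[k + 1L] > val[k]) k else k + 1L
      } else {
        if (val[k + 1L] < val[k]) k else k + 1L
      }
      idx <- idx[-drop]; val <- val[-drop]; typ <- typ[-drop]
    }
    list(idx = idx, val = val, typ = typ)
  }
  a <- fix_alt(idx, val, typ)
  repeat {
    if (length(a$idx) < 2L) break
    d <- abs(diff(a$val))
    k <- which.min(d)
    if (d[k] >= min_sep) break
    keep <- setdiff(seq_along(a$idx), c(k, k + 1L))
    a <- fix_alt(a$idx[keep], a$val[keep], a$typ[keep])
  }
  data.frame(idx = a$idx, value = a$val, type = a$typ,
             stringsAsFactors = FALSE)
}

oracle_cycles <- function(x, fs, min_sep) {
  lm <- oracle_landmarks(x, min_sep)
  if (nrow(lm) > 0L && lm$type[1L] != "min") lm <- lm[-1L, , drop = FALSE]
  n_cyc <- (nrow(lm) - 1L) %/% 2L
  if (is.na(n_cyc) || n_cyc < 1L) return(NULL)
  i_on <- seq(1L, by = 2L, length.out = n_cyc)
  data.frame(t_onset = (lm$idx[i_on] - 1) / fs,
             t_peak = (lm$idx[i_on + 1L] - 1) / fs,
             t_offset = (lm$idx[i_on + 2L] - 1) / fs,
             v_onset = lm$value[i_on],
             v_peak = lm$value[i_on + 1L],
             v_offset = lm$value[i_on + 2L])
}

# linear-interpolation percentile on the sorted sample (type-7 convention)
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  s[lo] + (h - floor(h)) * (s[hi] - s[lo])
}

# per-window sort-based median of trough values
oracle_rel <- function(trough_t, trough_v, t, window_s) {
  sel <- trough_t >= t - window_s / 2 & trough_t <= t + window_s / 2
  if (!any(sel)) return(median(trough_v))
  v <- sort(trough_v[sel])
  n <- length(v)
  if (n %% 2L == 1L) v[(n + 1L) / 2L] else (v[n / 2L] + v[n / 2L + 1L]) / 2
}

# sort-and-sweep merge of one speaker's intervals
oracle_merge <- function(s, e, min_pause) {
  o <- order(s); s <- s[o]; e <- e[o]
  out_s <- s[1L]; out_e <- e[1L]
  for (i in seq_along(s)[-1L]) {
    if (s[i] - out_e[length(out_e)] < min_pause) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], e[i])
    } else {
      out_s <- c(out_s, s[i]); out_e <- c(out_e, e[i])
    }
  }
  data.frame(t_start = out_s, t_end = out_e)
}

# grid-based chronogram oracle: discretise speech activity on a fine
# grid, read silences off the global occupancy, classify overlaps from
# pairwise activity
oracle_chronogram <- function(ts, grid = 0.01) {
  t_max <- max(ts$t_end) + 1
  n <- ceiling(t_max / grid)
  occ <- matrix(FALSE, n, length(unique(ts$speaker)),
                dimnames = list(NULL, sort(unique(ts$speaker))))
  for (i in seq_len(nrow(ts))) {
    a <- floor(ts$t_start[i] / grid) + 1L
    b <- ceiling(ts$t_end[i] / grid)
    occ[a:b, ts$speaker[i]] <- TRUE
  }
  any_on <- rowSums(occ) > 0
  ev <- list()
  r <- rle(any_on)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(!r$values)) {
    if (starts[k] == 1L || ends[k] == n) next
    gs <- (starts[k] - 1L) * grid; ge <- ends[k] * grid
    prev <- ts[abs(ts$t_end - gs) < grid, , drop = FALSE]
    nxt <- ts[abs(ts$t_start - ge) < grid, , drop = FALSE]
    if (nrow(prev) == 0L || nrow(nxt) == 0L) next
    prev <- prev[which.max(prev$t_end - prev$t_start), ]
    nxt <- nxt[which.max(nxt$t_end - nxt$t_start), ]
    ev[[length(ev) + 1L]] <- data.frame(
      base = if (prev$speaker == nxt$speaker) "WSS" else "BSS",
      prev_speaker = prev$speaker, next_speaker = nxt$speaker,
      t_start = prev$t_end, t_end = nxt$t_start,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(ts))) {
    for (j in seq_len(nrow(ts))) {
      if (i == j || ts$speaker[i] == ts$speaker[j]) next
      if (ts$t_start[j] > ts$t_start[i] && ts$t_start[j] < ts$t_end[i]) {
        if (ts$t_end[j] <= ts$t_end[i]) {
          ev[[length(ev) + 1L]] <- data.frame(
            base = "WSO", prev_speaker = ts$speaker[i],
            next_speaker = ts$speaker[i],
            t_start = ts$t_start[j], t_end = ts$t_end[j],
            stringsAsFactors = FALSE)
        } else {
          ev[[length(ev) + 1L]] <- data.frame(
            base = "BSO", prev_speaker = ts$speaker[i],
            next_speaker = ts$speaker[j],
            t_start = ts$t_start[j], t_end = ts$t_end[i],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(ev)) return(NULL)
  out <- do.call(rbind, ev)
  out[order(out$t_start, out$t_end, out$base), , drop = FALSE]
}

# random zigzag trace with amplitudes clearly above or below min_sep;
# the first and last segments are always supra-threshold so that the
# comparison probes the interior pruning logic, not boundary conventions
random_zigzag <- function(n_seg = sample(6:14, 1), fs = 100, min_sep = 1) {
  v <- 0
  t <- 0
  bp_t <- 0; bp_v <- 0
  up <- TRUE
  for (k in seq_len(n_seg)) {
    amp <- if (k <= 2L || k >= n_seg - 1L || runif(1) < 0.7) {
      runif(1, 1.3, 3)
    } else {
      runif(1, 0.15, 0.7)
    }
    v <- if (up) v + amp else v - amp
    t <- t + runif(1, 0.4, 1.5)
    bp_t <- c(bp_t, t); bp_v <- c(bp_v, v)
    up <- !up
  }
  tt <- seq(0, t, by = 1 / fs)
  y <- approx(bp_t, bp_v, xout = tt)$y
  rip_trace(y, fs, "z", "zscored")
}

# random multi-speaker talkspurt layout; same-speaker gaps >= 0.3 s and
# all boundary pairs separated by >= 0.05 s so that grid matching in the
# oracle is unambiguous
random_layout <- function(n_speakers = 3, t_max = 40) {
  repeat {
    rows <- list()
    for (sp in paste0("S", seq_len(n_speakers))) {
      t <- runif(1, 0, 4)
      while (t < t_max) {
        d <- runif(1, 0.4, 3)
        rows[[length(rows) + 1L]] <- data.frame(
          speaker = sp, t_start = t, t_end = t + d,
          stringsAsFactors = FALSE)
        t <- t + d + runif(1, 0.35, 6)
      }
    }
    ts <- do.call(rbind, rows)
    b <- sort(c(ts$t_start, ts$t_end))
    if (min(diff(b)) >= 0.05) return(ts)
  }
}

# minimal cycle table builder for unit tests
make_cycles <- function(t_onset, t_peak, t_offset, v_onset, v_peak,
                        v_offset, speaker = "a", silent = NA) {
  data.frame(speaker = speaker, cycle = seq_along(t_onset),
             t_onset = t_onset, t_peak = t_peak, t_offset = t_offset,
             v_onset = v_onset, v_peak = v_peak, v_offset = v_offset,
             silent = silent, stringsAsFactors = FALSE)
}
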