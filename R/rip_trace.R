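#' RIP trace objects
#'
#' A `rip_trace` holds one speaker's uniformly sampled lung-volume proxy
#' (the weighted-sum respiratory inductance plethysmography signal) together
#' with its sample rate and calibration state. The calibration state tracks
#' the normalisation applied so far: `"raw"` (belt units), `"zscored"`
#' (whole-conversation standardisation) or `"sv_units"` (levels expressed as
#' fractions of the speaker's speaking volume, with the dynamic resting
#' expiratory level mapped to 0).
#'
#' @param samples numeric vector of lung-volume values (length >= 2, finite).
#' @param sample_rate sampling rate in Hz (> 0).
#' @param speaker_id speaker identifier.
#' @param calibration one of `"raw"`, `"zscored"`, `"sv_units"`.
#' @param t0 time of the first sample in seconds.
#' @return An object of class `rip_trace`.
#' @export
rip_trace <- function(samples, sample_rate, speaker_id = "spk",
                      calibration = c("raw", "zscored", "sv_units"),
                      t0 = 0) {
  calibration <- match.arg(calibration)
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("a rip_trace needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("rip_trace samples must all be finite", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be a single positive number", call. = FALSE)
  }
  structure(
    list(speaker_id = as.character(speaker_id),
         samples = samples,
         sample_rate = as.numeric(sample_rate),
         calibration = calibration,
         t0 = as.numeric(t0)),
    class = "rip_trace"
  )
}

#' @export
print.rip_trace <- function(x, ...) {
  cat(sprintf(
    "<rip_trace> speaker %s: %d samples @ %g Hz (%.1f s), calibration: %s\n",
    x$speaker_id, length(x$samples), x$sample_rate,
    length(x$samples) / x$sample_rate, x$calibration))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param trace a [rip_trace()].
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$sample_rate
}

#' Resample a trace to a uniform working rate
#'
#' Linear interpolation onto a uniform grid. Breathing energy lives well
#' below 2 Hz, so linear interpolation at the default 100 Hz working rate
#' does not distort the signal.
#'
#' @param trace a [rip_trace()].
#' @param rate target rate in Hz (default 100).
#' @return a [rip_trace()] at the new rate.
#' @export
resample_trace <- function(trace, rate = 100) {
  stopifnot(inherits(trace, "rip_trace"))
  if (isTRUE(all.equal(rate, trace$sample_rate))) {
    return(trace)
  }
  tt <- trace_times(trace)
  new_t <- seq(tt[1], tt[length(tt)], by = 1 / rate)
  y <- stats::approx(tt, trace$samples, xout = new_t, rule = 2)$y
  rip_trace(y, rate, trace$speaker_id, trace$calibration, t0 = tt[1])
}

#' Standardise a trace over the whole conversation
#'
#' Subtracts the sample mean and divides by the sample standard deviation,
#' computed over the full trace. Segmentation landmarks are defined on this
#' z-scored signal (peaks and troughs separated by at least one standard
#' deviation).
#'
#' @param trace a raw [rip_trace()].
#' @return the z-scored trace (`calibration = "zscored"`).
#' @export
zscore_trace <- function(trace) {
  stopifnot(inherits(trace, "rip_trace"))
  if (trace$calibration != "raw") {
    stop("zscore_trace() expects a raw trace", call. = FALSE)
  }
  s <- stats::sd(trace$samples)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate signal: constant trace cannot be z-scored", call. = FALSE)
  }
  out <- trace
  out$samples <- (trace$samples - mean(trace$samples)) / s
  out$calibration <- "zscored"
  out
}
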