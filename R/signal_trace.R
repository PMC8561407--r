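#' Construct a uniformly sampled signal trace
#'
#' The basic container for one channel of a recording: a numeric sample
#' vector at a fixed rate, with a unit label, a channel label and the start
#' time of the first sample. RIP band signals are in arbitrary inductance
#' units (a.u.), spirometer channels in L/s (flow) or L (volume).
#'
#' @param samples Numeric vector of samples; must be finite.
#' @param rate Sampling rate in Hz (> 0).
#' @param unit Unit label, e.g. `"a.u."`, `"L/s"`, `"L"`.
#' @param channel Channel label, e.g. `"thoracic"`.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `rip_trace`.
#' @examples
#' tr <- signal_trace(sin(seq(0, 2 * pi, length.out = 100)), rate = 50)
#' trace_duration(tr)
#' @export
signal_trace <- function(samples, rate, unit = "a.u.", channel = "signal", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    abort("`rate` must be a single positive number.")
  }
  if (length(samples) && !all(is.finite(samples))) {
    bad <- which(!is.finite(samples))[1]
    abort(sprintf("non-finite sample at index %d in channel '%s'", bad, channel))
  }
  structure(
    list(samples = samples, rate = as.numeric(rate), unit = unit,
         channel = channel, t0 = as.numeric(t0)),
    class = "rip_trace"
  )
}

is_trace <- function(x) inherits(x, "rip_trace")

#' Sample times of a trace
#' @param trace A [signal_trace()].
#' @return Numeric vector of times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(is_trace(trace))
  if (!length(trace$samples)) return(numeric(0))
  trace$t0 + (seq_along(trace$samples) - 1) / trace$rate
}

#' Duration of a trace in seconds
#' @inheritParams trace_times
#' @return Duration spanned by the samples (0 for traces with < 2 samples).
#' @export
trace_duration <- function(trace) {
  stopifnot(is_trace(trace))
  if (length(trace$samples) < 2) return(0)
  (length(trace$samples) - 1) / trace$rate
}

#' @export
print.rip_trace <- function(x, ...) {
  cat(sprintf("<rip_trace> %s [%s], %d samples @ %g Hz, t0 = %g s\n",
              x$channel, x$unit, length(x$samples), x$rate, x$t0))
  invisible(x)
}

#' @export
as_tibble.rip_trace <- function(x, ...) {
  tibble(time_s = trace_times(x), value = x$samples)
}

# Linear-interpolation resampling onto a uniform grid at `rate`, starting at
# `t0` (defaults to the trace's own start), covering the trace support.
resample_trace <- function(trace, rate, t0 = trace$t0, t_end = NULL) {
  stopifnot(is_trace(trace))
  if (is.null(t_end)) t_end <- trace$t0 + trace_duration(trace)
  if (t_end <= t0 || !length(trace$samples)) {
    return(signal_trace(numeric(0), rate, trace$unit, trace$channel, t0))
  }
  grid <- seq(t0, t_end, by = 1 / rate)
  y <- approx(trace_times(trace), trace$samples, xout = grid, rule = 2)$y
  signal_trace(y, rate, trace$unit, trace$channel, t0)
}

# Crop to the half-open interval [t_start, t_end).
crop_trace <- function(trace, t_start, t_end) {
  stopifnot(is_trace(trace))
  tt <- trace_times(trace)
  keep <- tt >= t_start - 1e-9 & tt < t_end - 1e-9
  first <- which(keep)[1]
  t0 <- if (is.na(first)) t_start else tt[first]
  signal_trace(trace$samples[keep], trace$rate, trace$unit, trace$channel, t0)
}
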