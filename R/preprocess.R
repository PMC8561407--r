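#' Savitzky-Golay smoothing of a trace
#'
#' Local least-squares polynomial smoothing; removes high-frequency noise
#' and movement artefacts while passing polynomial trends of degree <=
#' `polyorder` through unchanged. The default 0.75 s window with a cubic
#' fit preserves breaths of >= 1 s while suppressing content above ~4 Hz.
#'
#' @param trace A [signal_trace()].
#' @param window_s Window length in seconds; the sample count is forced odd.
#' @param polyorder Polynomial order of the local fit.
#' @return A smoothed [signal_trace()] of identical length and rate.
#' @export
savgol_smooth <- function(trace, window_s = 0.75, polyorder = 3) {
  stopifnot(is_trace(trace))
  n_w <- round(window_s * trace$rate)
  if (n_w %% 2 == 0) n_w <- n_w + 1
  if (n_w < polyorder + 2) {
    abort(sprintf("window of %d samples is too short for polyorder %d (need >= %d)",
                  n_w, polyorder, polyorder + 2))
  }
  if (length(trace$samples) <= n_w) {
    abort("trace shorter than the smoothing window")
  }
  y <- signal::sgolayfilt(trace$samples, p = polyorder, n = n_w)
  signal_trace(y, trace$rate, trace$unit, trace$channel, trace$t0)
}

#' Sum the thoracic and abdominal band signals
#'
#' The two RIP bands are combined into one volume-proportional signal by
#' sample-wise addition over their common support; if the rates differ, the
#' faster trace is resampled down first.
#'
#' @param thoracic,abdominal [signal_trace()]s in the same unit.
#' @return A [signal_trace()] labelled `rip_sum`.
#' @export
sum_bands <- function(thoracic, abdominal) {
  stopifnot(is_trace(thoracic), is_trace(abdominal))
  if (thoracic$unit != abdominal$unit) {
    abort(sprintf("band units differ: '%s' vs '%s'", thoracic$unit, abdominal$unit))
  }
  rate <- min(thoracic$rate, abdominal$rate)
  t0 <- max(thoracic$t0, abdominal$t0)
  t_end <- min(thoracic$t0 + trace_duration(thoracic),
               abdominal$t0 + trace_duration(abdominal))
  if (t_end <= t0) abort("bands have no overlapping support")
  a <- resample_trace(thoracic, rate, t0, t_end)
  b <- resample_trace(abdominal, rate, t0, t_end)
  n <- min(length(a$samples), length(b$samples))
  signal_trace(a$samples[1:n] + b$samples[1:n], rate, thoracic$unit,
               "rip_sum", t0)
}

#' Integrate spirometer flow to volume
#'
#' Cumulative trapezoidal integration of the flow signal (L/s -> L). With
#' `detrend = TRUE` (default) a linear drift term fitted over the whole
#' segment is removed afterwards, which stabilises the volume baseline
#' against small sensor offsets; breath-to-breath amplitudes are unaffected
#' to first order.
#'
#' @param flow A [signal_trace()] of flow in L/s.
#' @param detrend Remove a fitted linear drift term? Default `TRUE`.
#' @return A [signal_trace()] of volume in L.
#' @export
integrate_flow <- function(flow, detrend = TRUE) {
  stopifnot(is_trace(flow))
  if (flow$unit != "L/s") abort("`flow` must be in L/s")
  tt <- trace_times(flow)
  if (length(tt) < 2) {
    return(signal_trace(numeric(length(tt)), flow$rate, "L", "spiro_volume", flow$t0))
  }
  vol <- c(pracma::cumtrapz(tt, flow$samples))
  if (detrend) {
    ctt <- tt - mean(tt)
    slope <- sum(ctt * (vol - mean(vol))) / sum(ctt^2)
    vol <- vol - (mean(vol) + slope * ctt)
  }
  signal_trace(vol, flow$rate, "L", "spiro_volume", flow$t0)
}

common_rate <- function(a, b) min(a$rate, b$rate)

# Remove a least-squares linear trend (baseline drift would otherwise bias
# the cross-correlation peak).
detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n) - (n + 1) / 2
  x - mean(x) - sum(t * (x - mean(x))) / sum(t^2) * t
}

#' Estimate the time lag between the RIP and spirometer signals
#'
#' Maximises the cross-correlation of the two mean-removed signals over a
#' bounded lag window. A positive value means the RIP recording runs behind
#' the spirometer recording by that many seconds.
#'
#' @param rip Summed RIP trace (a.u.).
#' @param spiro_volume Spirometer volume trace (L).
#' @param max_lag_s Half-width of the lag search window in seconds.
#' @return The lag in seconds, quantised to the common sample period.
#' @export
estimate_lag <- function(rip, spiro_volume, max_lag_s = 5) {
  stopifnot(is_trace(rip), is_trace(spiro_volume))
  if (trace_duration(rip) < 10 || trace_duration(spiro_volume) < 10) {
    abort("lag estimation needs at least 10 s of signal on both devices")
  }
  rate <- common_rate(rip, spiro_volume)
  x <- detrend_linear(resample_trace(rip, rate)$samples)
  y <- detrend_linear(resample_trace(spiro_volume, rate)$samples)
  if (sd(x) == 0 || sd(y) == 0) abort("flat (zero-variance) input to estimate_lag")
  k_max <- round(max_lag_s * rate)
  m <- length(y)
  # fixed central template of the reference signal, slid within the RIP
  # signal: a constant overlap keeps the broad correlation peak of slow
  # breathing signals from being tilted by edge effects
  j0 <- min(k_max + 1L, max(1L, m %/% 4L))
  j1 <- max(m - k_max, m - m %/% 4L + 1L)
  if (j1 <= j0) {
    j0 <- 1L
    j1 <- m
  }
  yt <- numeric(m)
  yt[j0:j1] <- y[j0:j1]
  e_y <- sum(yt^2)
  n_need <- j1 + k_max
  xp <- c(x, numeric(max(0, n_need - length(x))))
  len <- stats::nextn(length(xp) + m, 2)
  X <- fft(c(xp, numeric(len - length(xp))))
  Y <- fft(c(yt, numeric(len - m)))
  cc <- Re(fft(X * Conj(Y), inverse = TRUE)) / len
  # cc[k + 1] (circular) holds sum_j y[j] * x[j + k]
  lags <- seq(-k_max, k_max)
  idx <- ifelse(lags >= 0, lags + 1, len + lags + 1)
  cs <- cumsum(c(0, xp^2))
  e_x <- cs[pmin(j1 + lags, length(xp)) + 1] -
    cs[pmax(j0 + lags, 1)]
  ncc <- cc[idx] / sqrt(pmax(e_x * e_y, .Machine$double.eps))
  # account for the RIP clock starting offset so the result is absolute time
  t_offset <- rip$t0 - spiro_volume$t0
  lags[which.max(ncc)] / rate + t_offset
}

#' Align the RIP and spirometer traces
#'
#' Shifts the RIP trace back by the estimated lag, resamples both signals
#' to the lower of the two device rates and crops them to the overlapping
#' time range, yielding equal-length, same-rate traces ready for breath
#' detection.
#'
#' @inheritParams estimate_lag
#' @param lag Lag in seconds, usually from [estimate_lag()].
#' @return A list of class `rip_aligned` with `rip_volume_raw` (a.u.),
#'   `spiro_volume` (L), `lag_applied` (s) and `rate` (Hz).
#' @export
align_traces <- function(rip, spiro_volume, lag) {
  stopifnot(is_trace(rip), is_trace(spiro_volume))
  rip2 <- rip
  rip2$t0 <- rip$t0 - lag
  rate <- common_rate(rip2, spiro_volume)
  t0 <- max(rip2$t0, spiro_volume$t0)
  t_end <- min(rip2$t0 + trace_duration(rip2),
               spiro_volume$t0 + trace_duration(spiro_volume))
  if (t_end <= t0) abort("no overlap between traces after lag correction")
  a <- resample_trace(rip2, rate, t0, t_end)
  b <- resample_trace(spiro_volume, rate, t0, t_end)
  n <- min(length(a$samples), length(b$samples))
  a$samples <- a$samples[1:n]
  b$samples <- b$samples[1:n]
  structure(list(rip_volume_raw = a, spiro_volume = b,
                 lag_applied = lag, rate = rate),
            class = "rip_aligned")
}

#' @export
print.rip_aligned <- function(x, ...) {
  cat(sprintf("<rip_aligned> %d samples @ %g Hz, lag applied %.3f s\n",
              length(x$spiro_volume$samples), x$rate, x$lag_applied))
  invisible(x)
}
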