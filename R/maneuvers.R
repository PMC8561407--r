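#' Simulate a spirometry maneuver volume trace
#'
#' Builds the reference volume signal (L) of a single maneuver. `"svc"` is
#' a slow maximal inspiration-expiration cycle of total excursion `svc`;
#' `"fvc"` is a maximal inspiration followed by a forced exponential
#' expiration `V(t) = top - fvc * (1 - exp(-t / tau))`, so
#' `FEV1 = fvc * (1 - exp(-1 / tau))` in closed form.
#'
#' @param type `"svc"` or `"fvc"`.
#' @param svc Slow vital capacity in L.
#' @param fvc Forced vital capacity in L.
#' @param tau Time constant of the forced expiration in seconds.
#' @param rate Sample rate in Hz.
#' @param noise_sd SD of additive Gaussian noise in L.
#' @param seed Optional seed for the noise draw.
#' @return A [signal_trace()] of volume in L.
#' @export
simulate_maneuver <- function(type = c("svc", "fvc"), svc = 4.2, fvc = 4.0,
                              tau = 0.5, rate = 100, noise_sd = 0,
                              seed = NULL) {
  type <- match.arg(type)
  build <- function() {
    h <- 1 / rate
    ramp <- function(from, to, dur) {
      n <- max(2, round(dur * rate))
      from + (to - from) * (1 - cos(pi * seq(0, 1, length.out = n))) / 2
    }
    hold <- function(level, dur) rep(level, max(1, round(dur * rate)))
    x <- if (type == "svc") {
      insp <- 0.45 * svc          # above quiet end-expiration
      c(hold(0, 2), ramp(0, insp, 4), hold(insp, 1),
        ramp(insp, insp - svc, 6), hold(insp - svc, 2))
    } else {
      top <- fvc
      t_exp <- seq(0, 4, by = h)
      c(hold(0, 2), ramp(0, top, 2), hold(top, 0.5),
        top - fvc * (1 - exp(-t_exp / tau)), hold(top - fvc * (1 - exp(-4 / tau)), 1))
    }
    if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
    signal_trace(x, rate, "L", paste0("maneuver_", type))
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Render a raw RIP trace from a maneuver volume signal
#'
#' Applies the garment measurement model to a known volume signal: an
#' optional saturating (sub-linear) response above `sat_threshold_L`
#' (excursions beyond the threshold are compressed by `sat_gain`), then the
#' combined gain, offset and additive noise. The saturation emulates a belt
#' response that is linear over the tidal range used for calibration but
#' compresses the much larger maneuver excursions.
#'
#' @param volume A [signal_trace()] of volume in L.
#' @param gain Combined gain in a.u. per L.
#' @param offset Offset in a.u.
#' @param sat_threshold_L Excursion (L, from the trace minimum) above which
#'   the response becomes sub-linear; `Inf` disables saturation.
#' @param sat_gain Slope of the response above the threshold, relative to
#'   the linear regime (0 < sat_gain <= 1).
#' @param noise_sd SD of additive Gaussian noise in a.u.
#' @param seed Optional seed for the noise draw.
#' @return A [signal_trace()] in a.u.
#' @export
render_rip_from_volume <- function(volume, gain, offset = 5,
                                   sat_threshold_L = Inf, sat_gain = 1,
                                   noise_sd = 0, seed = NULL) {
  stopifnot(is_trace(volume))
  build <- function() {
    v <- volume$samples - min(volume$samples)
    over <- v > sat_threshold_L
    v[over] <- sat_threshold_L + (v[over] - sat_threshold_L) * sat_gain
    x <- gain * v + offset
    if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
    signal_trace(x, volume$rate, "a.u.", "rip_maneuver", volume$t0)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

# Light quadratic-reproducing smoothing (0.2 s window) applied before
# extraction; without it, the max-minus-min estimators inflate under sample
# noise by the expected range of the noise extremes.
smooth_maneuver <- function(volume) {
  x <- volume$samples
  w <- round(0.2 * volume$rate)
  if (w %% 2 == 0) w <- w + 1
  if (w >= 5 && length(x) > w) x <- signal::sgolayfilt(x, p = 2, n = w)
  x
}

#' Extract slow vital capacity from a maneuver volume trace
#'
#' SVC is the total excursion of the slow maneuver: `max(volume) -
#' min(volume)`. A near-flat trace (excursion < 0.1 L) is flagged invalid
#' via a warning and the `valid` attribute.
#'
#' @param volume A [signal_trace()] of volume in L.
#' @return SVC in litres (attribute `valid`).
#' @export
extract_svc <- function(volume) {
  stopifnot(is_trace(volume))
  if (!length(volume$samples)) abort("empty maneuver trace")
  x <- smooth_maneuver(volume)
  svc <- max(x) - min(x)
  valid <- svc >= 0.1
  if (!valid) warn(sprintf("maneuver excursion %.3f L is implausibly small; flagged invalid", svc))
  structure(svc, valid = valid)
}

#' Extract FVC and FEV1 from a forced-expiration volume trace
#'
#' The start of the forced expiration is located by back-extrapolation: the
#' tangent at the point of steepest descent is intersected with the
#' pre-expiratory plateau (the maximum volume reached before that point).
#' FVC is the plateau level minus the post-expiratory minimum; FEV1 is the
#' volume expired in the first second after the back-extrapolated start.
#'
#' @param volume A [signal_trace()] of volume in L containing one forced
#'   expiration.
#' @param min_descent_L_s Minimum expiratory descent rate (L/s) below which
#'   no forced expiration is recognised.
#' @return A one-row tibble with `fvc` and `fev1` in litres
#'   (`fev1 <= fvc` always).
#' @export
extract_fvc_fev1 <- function(volume, min_descent_L_s = 1) {
  stopifnot(is_trace(volume))
  # no pre-smoothing: a quadratic smoother overshoots at the sharp corner of
  # a forced expiration; only the derivative estimate below is smoothed
  x <- volume$samples
  n <- length(x)
  if (n < 5) abort("maneuver trace too short")
  rate <- volume$rate
  # quadratic-reproducing smoothed derivative; window ~50 ms
  w <- max(5, round(0.05 * rate))
  if (w %% 2 == 0) w <- w + 1
  dx <- signal::sgolayfilt(x, p = 2, n = w, m = 1, ts = 1 / rate)
  i_star <- which.min(dx)
  slope <- dx[i_star]
  if (slope > -min_descent_L_s) {
    abort(sprintf("no forced expiration found (steepest descent %.2f L/s)", slope))
  }
  plateau <- max(x[1:i_star])
  # tangent: x[i_star] + slope * (t - t_star) == plateau
  t_star <- (i_star - 1) / rate
  t0 <- t_star + (plateau - x[i_star]) / slope
  i0 <- max(1, min(n, round(t0 * rate) + 1))
  fvc <- plateau - min(x[i0:n])
  t1 <- t0 + 1
  if (t1 > (n - 1) / rate) abort("trace ends less than 1 s after expiration start")
  v1 <- approx((seq_len(n) - 1) / rate, x, xout = t1)$y
  fev1 <- plateau - v1
  fev1 <- min(max(fev1, 0), fvc)
  tibble(fvc = fvc, fev1 = fev1)
}

#' Maneuver volumes from a calibrated RIP trace
#'
#' Calibrates a raw RIP maneuver trace with the subject's "sitting"-task
#' calibration model (slope and intercept applied sample-wise), then
#' extracts the requested parameters.
#'
#' @param rip_trace Raw RIP maneuver [signal_trace()] (a.u.).
#' @param sitting_model The subject's sitting-task [fit_calibration()]
#'   model.
#' @param type `"svc"` or `"fvc"`.
#' @return A one-row tibble with `svc_L` or `fvc_L`/`fev1_L`.
#' @export
rip_maneuver_volumes <- function(rip_trace, sitting_model, type = c("svc", "fvc")) {
  type <- match.arg(type)
  stopifnot(is_trace(rip_trace))
  if (!inherits(sitting_model, "rip_calibration")) {
    abort("a sitting-task calibration model is required")
  }
  cal <- signal_trace(sitting_model$a * rip_trace$samples + sitting_model$b,
                      rip_trace$rate, "L", rip_trace$channel, rip_trace$t0)
  if (type == "svc") {
    tibble(svc_L = as.numeric(extract_svc(cal)))
  } else {
    res <- extract_fvc_fev1(cal)
    tibble(fvc_L = res$fvc, fev1_L = res$fev1)
  }
}

#' Bland-Altman agreement of maneuver volumes in litres
#'
#' Pools all paired trials across subjects into one Bland-Altman analysis
#' per lung parameter, on spirometer-minus-RIP differences in litres.
#' The a priori criterion is a limits-of-agreement half-width of at most
#' 0.150 L.
#'
#' @param results Tibble of maneuver results with columns `subject`,
#'   `session`, `trial`, `device` (`"spiro"`/`"rip"`), `parameter`
#'   (`"svc"`, `"fvc"`, `"fev1"`) and `value_L`.
#' @param loa_limit_L Criterion bound in litres (default 0.150).
#' @return A tibble with one row per (session, parameter): `bias_L`,
#'   `loa_halfwidth_L`, `n`, `meets_loa`.
#' @export
volume_agreement <- function(results, loa_limit_L = 0.150) {
  wide <- tidyr::pivot_wider(results, names_from = "device",
                             values_from = "value_L")
  if (!all(c("spiro", "rip") %in% names(wide))) {
    abort("`results` must contain both devices")
  }
  wide <- wide[!is.na(wide$spiro) & !is.na(wide$rip), ]
  wide |>
    dplyr::group_by(.data$session, .data$parameter) |>
    dplyr::summarise(
      bias_L = mean(.data$spiro - .data$rip),
      loa_halfwidth_L = 1.96 * sd(.data$spiro - .data$rip),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(meets_loa = .data$loa_halfwidth_L <= loa_limit_L)
}
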