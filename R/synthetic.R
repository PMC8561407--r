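#' Default per-task breathing parameters
#'
#' Task-specific tidal-volume and respiratory-rate distributions for the
#' seven tasks of daily living in the study protocol, plus default
#' motion-artefact rates (demanding tasks are more artefact-prone).
#' Tidal volumes are anchored to the printed task extremes (bend-over
#' sitting 0.67 (SD 0.14) L, stair climbing 1.57 (SD 0.48) L); the
#' remaining tasks interpolate plausibly between quiet rest and exercise.
#'
#' @return A tibble with columns `task`, `tv_mean` (L), `tv_sd` (L),
#'   `rr_mean` (breaths/min), `rr_sd` (breaths/min), `artefact_rate`
#'   (events/min).
#' @export
default_task_table <- function() {
  tibble::tribble(
    ~task,               ~tv_mean, ~tv_sd, ~rr_mean, ~rr_sd, ~artefact_rate,
    "lying",                 0.80,   0.15,       12,      1,            0.0,
    "sitting",               0.70,   0.14,       14,      2,            0.0,
    "standing",              0.75,   0.15,       14,      2,            0.0,
    "bend_over_sitting",     0.67,   0.14,       14,      2,            0.5,
    "vacuuming",             1.20,   0.30,       18,      3,            2.0,
    "walking_weights",       1.30,   0.35,       20,      3,            2.0,
    "stair_climbing",        1.57,   0.48,       24,      4,            3.0
  )
}

#' Scenario configuration for the synthetic dual-device dataset
#'
#' Describes a full two-session, multi-subject validation experiment:
#' per-task breathing distributions, the thoraco-abdominal volume split,
#' per-band gains and offsets of the RIP garment, the between-session gain
#' change that models garment reapplication, baseline drift, additive
#' noise, motion-artefact bursts, the inter-device time lag and the two
#' device sample rates.
#'
#' @param n_subjects Number of simulated subjects.
#' @param tasks Per-task parameter table, see [default_task_table()].
#' @param task_duration Duration of each task segment in seconds.
#' @param thoracic_fraction Fraction of each breath's volume expressed in
#'   the thoracic band, in (0, 1).
#' @param band_gain_thoracic,band_gain_abdominal Band gains in a.u. per L.
#' @param band_offset Static per-band offset in a.u.
#' @param subject_gain_sd SD of the log-normal per-subject multiplier
#'   applied to both band gains (garment fit differs between subjects).
#' @param amp_jitter_sd Relative SD of the per-breath RIP amplitude error
#'   (breath-to-breath variation in belt coupling), dimensionless.
#' @param session2_gain_multiplier Multiplier applied to both band gains in
#'   session 2, modelling the changed garment position after reapplication.
#' @param session2_offset_delta Additive change of `band_offset` in session 2.
#' @param drift_rate Linear baseline drift per band in a.u./s.
#' @param noise_sd SD of additive white Gaussian sample noise per band (a.u.).
#' @param artefact_amplitude Amplitude of motion-artefact bursts in a.u.
#' @param artefact_duration_s Duration of one artefact burst in seconds.
#' @param device_lag Delay of the RIP recording relative to the spirometer
#'   recording, in seconds (may be negative).
#' @param sample_rate_rip,sample_rate_spiro Device sample rates in Hz.
#' @param seed Master seed; all per-segment streams are derived from it.
#' @return An object of class `rip_scenario`.
#' @examples
#' cfg <- scenario_config(n_subjects = 2, task_duration = 60)
#' cfg$tasks$task
#' @export
scenario_config <- function(n_subjects = 15,
                            tasks = default_task_table(),
                            task_duration = 300,
                            thoracic_fraction = 0.6,
                            band_gain_thoracic = 2.0,
                            band_gain_abdominal = 1.0,
                            band_offset = 5.0,
                            subject_gain_sd = 0.10,
                            amp_jitter_sd = 0.03,
                            session2_gain_multiplier = 1.1,
                            session2_offset_delta = 0.0,
                            drift_rate = 0.01,
                            noise_sd = 0.02,
                            artefact_amplitude = 4.0,
                            artefact_duration_s = 2.0,
                            device_lag = 0.8,
                            sample_rate_rip = 128,
                            sample_rate_spiro = 100,
                            seed = 1L) {
  tasks <- as_tibble(tasks)
  req <- c("task", "tv_mean", "tv_sd", "rr_mean", "rr_sd")
  if (!all(req %in% names(tasks))) {
    abort(paste("`tasks` must have columns:", paste(req, collapse = ", ")))
  }
  if (!"artefact_rate" %in% names(tasks)) tasks$artefact_rate <- 0
  if (any(tasks$tv_mean <= 0)) abort("tv_mean must be > 0 for every task")
  nonneg <- c(tasks$tv_sd, tasks$rr_sd, tasks$artefact_rate, task_duration,
              drift_rate >= -Inf, noise_sd, subject_gain_sd, amp_jitter_sd,
              artefact_duration_s)
  if (any(c(tasks$tv_sd, tasks$rr_sd, tasks$artefact_rate, noise_sd,
            subject_gain_sd, amp_jitter_sd) < 0) || task_duration <= 0) {
    abort("rates, durations and SDs must be nonnegative (duration positive)")
  }
  if (any(tasks$rr_mean <= 0)) abort("rr_mean must be > 0")
  if (thoracic_fraction <= 0 || thoracic_fraction >= 1) {
    abort("thoracic_fraction must lie strictly inside (0, 1)")
  }
  if (sample_rate_rip <= 0 || sample_rate_spiro <= 0) abort("sample rates must be > 0")
  structure(
    list(n_subjects = as.integer(n_subjects), tasks = tasks,
         task_duration = task_duration, thoracic_fraction = thoracic_fraction,
         band_gain_thoracic = band_gain_thoracic,
         band_gain_abdominal = band_gain_abdominal,
         band_offset = band_offset, subject_gain_sd = subject_gain_sd,
         amp_jitter_sd = amp_jitter_sd,
         session2_gain_multiplier = session2_gain_multiplier,
         session2_offset_delta = session2_offset_delta,
         drift_rate = drift_rate, noise_sd = noise_sd,
         artefact_amplitude = artefact_amplitude,
         artefact_duration_s = artefact_duration_s,
         device_lag = device_lag, sample_rate_rip = sample_rate_rip,
         sample_rate_spiro = sample_rate_spiro, seed = as.integer(seed)),
    class = "rip_scenario"
  )
}

#' @export
print.rip_scenario <- function(x, ...) {
  cat(sprintf("<rip_scenario> %d subjects, %d tasks x %g s, seed %d\n",
              x$n_subjects, nrow(x$tasks), x$task_duration, x$seed))
  invisible(x)
}

task_row <- function(config, task) {
  i <- match(task, config$tasks$task)
  if (is.na(i)) {
    abort(sprintf("unknown task label '%s' (configured: %s)", task,
                  paste(config$tasks$task, collapse = ", ")))
  }
  config$tasks[i, ]
}

rtrunc_norm <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Generate a ground-truth breath train for one task segment
#'
#' Breath durations are drawn from the task's respiratory-rate distribution
#' (durations truncated > 1 s) and tidal volumes from its tidal-volume
#' distribution (truncated > 0.05 L). Breaths are laid back-to-back from
#' time 0 until the configured task duration is covered.
#'
#' @param config A [scenario_config()].
#' @param task Task label (must appear in `config$tasks`).
#' @param subject_seed Optional integer seed; when given, the draw is made
#'   under this seed without disturbing the caller's RNG.
#' @return A tibble (the ground-truth breath table) with columns
#'   `breath_index`, `t_start_s`, `duration_s`, `t_insp_end_s` (time of
#'   end-inspiration) and `tv_L`.
#' @examples
#' cfg <- scenario_config(n_subjects = 1, task_duration = 60)
#' tr <- generate_breath_train(cfg, "lying", subject_seed = 7)
#' mean(tr$tv_L)
#' @export
generate_breath_train <- function(config, task, subject_seed = NULL) {
  row <- task_row(config, task)
  draw <- function() {
    t_cum <- 0
    dur <- numeric(0)
    tv <- numeric(0)
    # oversample in chunks; duration = 60/RR truncated > 1 s
    while (t_cum < config$task_duration) {
      n <- max(16, ceiling((config$task_duration - t_cum) / (60 / row$rr_mean)))
      rr <- rtrunc_norm(n, row$rr_mean, row$rr_sd, lower = 1e-3)
      d <- 60 / rr
      redo <- which(d <= 1)
      while (length(redo)) {
        rr2 <- rtrunc_norm(length(redo), row$rr_mean, row$rr_sd, lower = 1e-3)
        d[redo] <- 60 / rr2
        redo <- redo[d[redo] <= 1]
      }
      v <- rtrunc_norm(n, row$tv_mean, row$tv_sd, lower = 0.05)
      dur <- c(dur, d)
      tv <- c(tv, v)
      t_cum <- sum(dur)
    }
    ends <- cumsum(dur)
    keep <- seq_len(which(ends >= config$task_duration)[1])
    dur <- dur[keep]
    tv <- tv[keep]
    starts <- c(0, cumsum(dur)[-length(dur)])
    tibble(
      breath_index = seq_along(dur),
      t_start_s = starts,
      duration_s = dur,
      t_insp_end_s = starts + dur / 2.5,
      tv_L = tv
    )
  }
  if (is.null(subject_seed)) draw() else with_seed(subject_seed, draw())
}

# Raised-cosine breath waveform. Inspiration occupies the first 1/2.5 of the
# breath (insp:exp = 1:1.5); volume above the end-expiratory baseline.
breath_volume_at <- function(truth, t) {
  if (!nrow(truth)) return(rep(0, length(t)))
  v <- numeric(length(t))
  idx <- findInterval(t, truth$t_start_s)
  inb <- idx >= 1
  if (!any(inb)) return(v)
  i <- idx[inb]
  phase <- t[inb] - truth$t_start_s[i]
  dur <- truth$duration_s[i]
  ti <- dur / 2.5
  te <- dur - ti
  tv <- truth$tv_L[i]
  insp <- phase < ti
  out <- numeric(sum(inb))
  out[insp] <- tv[insp] / 2 * (1 - cos(pi * phase[insp] / ti[insp]))
  ex <- !insp & phase < dur
  out[ex] <- tv[ex] / 2 * (1 + cos(pi * (phase[ex] - ti[ex]) / te[ex]))
  v[inb] <- out
  v
}

breath_flow_at <- function(truth, t) {
  if (!nrow(truth)) return(rep(0, length(t)))
  f <- numeric(length(t))
  idx <- findInterval(t, truth$t_start_s)
  inb <- idx >= 1
  if (!any(inb)) return(f)
  i <- idx[inb]
  phase <- t[inb] - truth$t_start_s[i]
  dur <- truth$duration_s[i]
  ti <- dur / 2.5
  te <- dur - ti
  tv <- truth$tv_L[i]
  insp <- phase < ti
  out <- numeric(sum(inb))
  out[insp] <- tv[insp] * pi / (2 * ti[insp]) * sin(pi * phase[insp] / ti[insp])
  ex <- !insp & phase < dur
  out[ex] <- -tv[ex] * pi / (2 * te[ex]) * sin(pi * (phase[ex] - ti[ex]) / te[ex])
  f[inb] <- out
  f
}

#' Render the spirometer flow trace for a breath train
#'
#' Produces the reference device's flow signal (L/s) from the ground-truth
#' breath table. Each breath is a raised-cosine inspiration followed by a
#' raised-cosine expiration; the inspiratory lobe integrates exactly to the
#' breath's tidal volume, and net volume over a breath is zero.
#'
#' @param truth Breath table from [generate_breath_train()].
#' @param rate Sample rate in Hz; must exceed twice the fastest breathing
#'   frequency.
#' @return A [signal_trace()] of flow in L/s starting at t = 0.
#' @export
render_spirometer_trace <- function(truth, rate) {
  if (!nrow(truth)) return(signal_trace(numeric(0), rate, "L/s", "spiro_flow"))
  f_max <- 1 / min(truth$duration_s)
  if (rate <= 2 * f_max) abort("spirometer rate must exceed 2x the fastest breath rate")
  t_end <- max(truth$t_start_s + truth$duration_s)
  t <- seq(0, t_end, by = 1 / rate)
  signal_trace(breath_flow_at(truth, t), rate, "L/s", "spiro_flow")
}

draw_artefact_windows <- function(rate_per_min, duration, width) {
  n <- rpois(1, rate_per_min * duration / 60)
  if (n == 0) return(tibble(start_s = numeric(0), end_s = numeric(0)))
  start <- sort(runif(n, 0, max(duration - width, 0)))
  tibble(start_s = start, end_s = start + width)
}

# Tapered band-limited burst added inside an artefact window: a sinusoid of
# random frequency (0.8-3 Hz, the band of gross body movement) and phase,
# which survives Savitzky-Golay smoothing, as real motion artefacts do.
add_artefacts <- function(x, t, windows, amplitude) {
  for (k in seq_len(nrow(windows))) {
    i <- which(t >= windows$start_s[k] & t < windows$end_s[k])
    if (!length(i)) next
    freq <- runif(1, 0.8, 3)
    phase <- runif(1, 0, 2 * pi)
    taper <- sin(pi * seq_along(i) / (length(i) + 1))
    x[i] <- x[i] + amplitude * taper * sin(2 * pi * freq * t[i] + phase)
  }
  x
}

#' Render the thoracic and abdominal RIP traces for a breath train
#'
#' The garment measurement model: each band reports its share of the breath
#' volume (set by `thoracic_fraction`) times a band gain, plus a static
#' offset, linear baseline drift, additive white noise and optional
#' motion-artefact bursts. A per-breath multiplicative amplitude jitter
#' (`amp_jitter_sd`) models breath-to-breath variation in belt coupling;
#' it is shared by the two bands. Session 2 multiplies both gains by
#' `session2_gain_multiplier` and shifts the offset by
#' `session2_offset_delta`. The whole RIP recording is delayed by
#' `device_lag` relative to the spirometer clock.
#'
#' In the noiseless, driftless case the summed tidal amplitude of the two
#' bands is exactly `gain_effective * TV`, with
#' `gain_effective = f * g_th + (1 - f) * g_ab` (times the per-subject and
#' per-session gain factors).
#'
#' @param truth Breath table from [generate_breath_train()].
#' @param config A [scenario_config()].
#' @param session Session number, 1 or 2.
#' @param subject_gain_factor Per-subject multiplier on both band gains.
#' @param artefact_rate Artefact events per minute (default: 0).
#' @param seed Optional seed for the noise/jitter/artefact draws.
#' @return A list with elements `thoracic` and `abdominal`
#'   ([signal_trace()]s in a.u.), `artefacts` (tibble of burst windows on
#'   the spirometer clock), `amp_jitter` (per-breath multiplicative factors)
#'   and `gain_effective` (combined a.u./L gain actually used).
#' @export
render_rip_traces <- function(truth, config, session = 1,
                              subject_gain_factor = 1,
                              artefact_rate = 0, seed = NULL) {
  if (!session %in% c(1, 2)) abort("`session` must be 1 or 2")
  render <- function() {
    rate <- config$sample_rate_rip
    m <- if (session == 2) config$session2_gain_multiplier else 1
    off <- config$band_offset +
      if (session == 2) config$session2_offset_delta else 0
    g_th <- config$band_gain_thoracic * subject_gain_factor * m
    g_ab <- config$band_gain_abdominal * subject_gain_factor * m
    f <- config$thoracic_fraction
    if (!nrow(truth)) {
      empty <- signal_trace(numeric(0), rate, "a.u.")
      return(list(thoracic = empty, abdominal = empty,
                  artefacts = tibble(start_s = numeric(0), end_s = numeric(0)),
                  amp_jitter = numeric(0),
                  gain_effective = (f * g_th + (1 - f) * g_ab)))
    }
    t_end <- max(truth$t_start_s + truth$duration_s) + max(config$device_lag, 0)
    t <- seq(0, t_end, by = 1 / rate)
    jit <- 1 + if (config$amp_jitter_sd > 0)
      rnorm(nrow(truth), 0, config$amp_jitter_sd) else numeric(nrow(truth))
    truth_j <- truth
    truth_j$tv_L <- truth$tv_L * jit
    # the garment clock runs `device_lag` behind the spirometer clock
    v <- breath_volume_at(truth_j, t - config$device_lag)
    wins <- draw_artefact_windows(artefact_rate,
                                  max(truth$t_start_s + truth$duration_s),
                                  config$artefact_duration_s)
    mk_band <- function(gain, share, label) {
      x <- gain * share * v + off + config$drift_rate * t
      if (config$noise_sd > 0) x <- x + rnorm(length(x), 0, config$noise_sd)
      if (nrow(wins)) {
        x <- add_artefacts(x, t, wins + config$device_lag,
                           config$artefact_amplitude / 2)
      }
      signal_trace(x, rate, "a.u.", label)
    }
    list(thoracic = mk_band(g_th, f, "thoracic"),
         abdominal = mk_band(g_ab, 1 - f, "abdominal"),
         artefacts = wins,
         amp_jitter = jit,
         gain_effective = f * g_th + (1 - f) * g_ab)
  }
  if (is.null(seed)) render() else with_seed(seed, render())
}

subject_gain_factor <- function(config, subject) {
  if (config$subject_gain_sd == 0) return(1)
  with_seed(derive_seed(config$seed, subject, 0L, 0L),
            exp(rnorm(1, 0, config$subject_gain_sd)))
}

#' Simulate one subject/session/task segment
#'
#' Draws the segment's ground truth and renders all three channels under a
#' reproducible sub-seed derived from the master seed, so any segment can be
#' regenerated in isolation.
#'
#' @inheritParams render_rip_traces
#' @param subject Subject index (1-based).
#' @param task Task label.
#' @return A list of class `rip_segment` with the three channel traces, the
#'   ground-truth breath table, artefact windows, true gains and lag.
#' @export
simulate_segment <- function(config, subject, session, task) {
  ti <- match(task, config$tasks$task)
  if (is.na(ti)) task_row(config, task) # raises the configuration error
  sseed <- derive_seed(config$seed, subject, session, ti)
  gf <- subject_gain_factor(config, subject)
  with_seed(sseed, {
    truth <- generate_breath_train(config, task)
    spiro <- render_spirometer_trace(truth, config$sample_rate_spiro)
    rip <- render_rip_traces(truth, config, session = session,
                             subject_gain_factor = gf,
                             artefact_rate = task_row(config, task)$artefact_rate)
  })
  structure(
    list(subject = subject, session = session, task = task,
         thoracic = rip$thoracic, abdominal = rip$abdominal,
         spiro_flow = spiro, truth = truth, artefacts = rip$artefacts,
         gain_effective = rip$gain_effective,
         gain_factor = gf, device_lag = config$device_lag),
    class = "rip_segment"
  )
}

#' @export
print.rip_segment <- function(x, ...) {
  cat(sprintf("<rip_segment> subject %d, session %d, task %s: %d breaths\n",
              x$subject, x$session, x$task, nrow(x$truth)))
  invisible(x)
}

#' Simulate a full multi-subject, two-session dataset
#'
#' @param config A [scenario_config()].
#' @param sessions Sessions to simulate (default both).
#' @param tasks Task labels to simulate (default all configured tasks).
#' @return An object of class `rip_dataset`: a list with `config`, the
#'   segment list, a pooled ground-truth breath tibble (`truth`) and a
#'   per-segment metadata tibble (`meta`).
#' @examples
#' ds <- simulate_dataset(scenario_config(n_subjects = 1, task_duration = 30,
#'                                        tasks = default_task_table()[1, ]))
#' nrow(ds$meta)
#' @export
simulate_dataset <- function(config, sessions = c(1L, 2L),
                             tasks = config$tasks$task) {
  grid <- expand.grid(subject = seq_len(config$n_subjects),
                      session = sessions, task = tasks,
                      stringsAsFactors = FALSE)
  segments <- vector("list", nrow(grid))
  truth_rows <- vector("list", nrow(grid))
  meta_rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    seg <- simulate_segment(config, grid$subject[i], grid$session[i], grid$task[i])
    segments[[i]] <- seg
    truth_rows[[i]] <- dplyr::mutate(seg$truth, subject = seg$subject,
                                     session = seg$session, task = seg$task,
                                     .before = 1)
    meta_rows[[i]] <- tibble(
      subject = seg$subject, session = seg$session, task = seg$task,
      n_breaths = nrow(seg$truth), gain_effective = seg$gain_effective,
      device_lag_s = seg$device_lag, n_artefacts = nrow(seg$artefacts)
    )
  }
  structure(
    list(config = config, segments = segments,
         truth = dplyr::bind_rows(truth_rows),
         meta = dplyr::bind_rows(meta_rows)),
    class = "rip_dataset"
  )
}

#' @export
print.rip_dataset <- function(x, ...) {
  cat(sprintf("<rip_dataset> %d segments (%d subjects), %d true breaths\n",
              length(x$segments), x$config$n_subjects, nrow(x$truth)))
  invisible(x)
}
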