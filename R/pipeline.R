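#' Processing parameters for the analysis pipeline
#'
#' All tunables of the processing chain in one validated list; each maps to
#' an argument of the stage function it controls.
#'
#' @param savgol_window_s Savitzky-Golay window in seconds.
#' @param savgol_polyorder Savitzky-Golay polynomial order.
#' @param detrend Remove linear drift from integrated spirometer volume?
#' @param max_lag_s Lag search half-window in seconds.
#' @param min_breath_s Minimum breath duration in seconds.
#' @param min_prominence_frac Breath-detection prominence fraction.
#' @param match_tol_s Breath matching tolerance in seconds.
#' @param tv_window Breath-averaging window (breaths).
#' @param bias_limit,loa_limit Task-level accuracy bounds in %.
#' @return A list of class `rip_params`.
#' @export
pipeline_params <- function(savgol_window_s = 0.75, savgol_polyorder = 3,
                            detrend = TRUE, max_lag_s = 5,
                            min_breath_s = 1, min_prominence_frac = 0.2,
                            match_tol_s = 0.5, tv_window = 5,
                            bias_limit = 5, loa_limit = 15) {
  stopifnot(savgol_window_s > 0, max_lag_s > 0, min_breath_s > 0,
            min_prominence_frac >= 0, match_tol_s > 0, tv_window >= 1)
  structure(list(savgol_window_s = savgol_window_s,
                 savgol_polyorder = savgol_polyorder, detrend = detrend,
                 max_lag_s = max_lag_s, min_breath_s = min_breath_s,
                 min_prominence_frac = min_prominence_frac,
                 match_tol_s = match_tol_s, tv_window = tv_window,
                 bias_limit = bias_limit, loa_limit = loa_limit),
            class = "rip_params")
}

#' Process one task segment through the measurement chain
#'
#' Smooths each RIP band, sums them, integrates spirometer flow to volume,
#' estimates and removes the inter-device lag, detects breaths on both
#' volume traces and matches them across devices.
#'
#' @param segment A `rip_segment` (from [simulate_segment()] or
#'   [load_dataset()]).
#' @param params A [pipeline_params()] list.
#' @return A list of class `rip_processed`: `match` ([match_breaths()]
#'   result), `tvs` (paired TV tibble, `NULL` when excluded), `lag_s`,
#'   `aligned`, plus the segment identifiers.
#' @export
process_segment <- function(segment, params = pipeline_params()) {
  stopifnot(inherits(segment, "rip_segment"))
  th <- savgol_smooth(segment$thoracic, params$savgol_window_s,
                      params$savgol_polyorder)
  ab <- savgol_smooth(segment$abdominal, params$savgol_window_s,
                      params$savgol_polyorder)
  rip <- sum_bands(th, ab)
  vol <- integrate_flow(segment$spiro_flow, detrend = params$detrend)
  lag <- estimate_lag(rip, vol, max_lag_s = params$max_lag_s)
  aligned <- align_traces(rip, vol, lag)
  spiro_breaths <- detect_breaths(aligned$spiro_volume, params$min_breath_s,
                                  params$min_prominence_frac)
  rip_breaths <- detect_breaths(aligned$rip_volume_raw, params$min_breath_s,
                                params$min_prominence_frac)
  match <- match_breaths(spiro_breaths, rip_breaths, params$match_tol_s)
  structure(
    list(subject = segment$subject, session = segment$session,
         task = segment$task, match = match,
         tvs = if (match$excluded) NULL else tv_series(match),
         lag_s = lag, aligned = aligned,
         spiro_breaths = spiro_breaths, rip_breaths = rip_breaths),
    class = "rip_processed"
  )
}

# Simulated maneuver set for measurement B: triplicate SVC and FVC trials
# per subject and session, both devices. RIP is rendered with the
# subject's session gains and a saturating response above the tidal range.
simulate_maneuver_set <- function(config, subjects = seq_len(config$n_subjects),
                                  sessions = c(1L, 2L), trials = 3,
                                  svc_mean = 4.2, fvc_mean = 4.0, tau = 0.5,
                                  trial_sd = 0.08, noise_sd_L = 0.02,
                                  sat_threshold_L = 2, sat_gain = 0.5) {
  rows <- list()
  traces <- list()
  for (sub in subjects) {
    gf <- subject_gain_factor(config, sub)
    base_gain <- config$thoracic_fraction * config$band_gain_thoracic +
      (1 - config$thoracic_fraction) * config$band_gain_abdominal
    sub_svc <- with_seed(derive_seed(config$seed, sub, 99L, 1L),
                         rnorm(1, svc_mean, 0.4))
    sub_fvc <- min(sub_svc, rnorm(1, fvc_mean, 0.4))
    for (ses in sessions) {
      m <- if (ses == 2) config$session2_gain_multiplier else 1
      gain <- base_gain * gf * m
      for (tr in seq_len(trials)) {
        sseed <- derive_seed(config$seed, sub, 90L + ses, tr)
        jit <- with_seed(sseed, rnorm(2, 0, trial_sd))
        svc_t <- max(1, sub_svc + jit[1])
        fvc_t <- max(1, min(svc_t, sub_fvc + jit[2]))
        svc_vol <- simulate_maneuver("svc", svc = svc_t, rate = config$sample_rate_spiro,
                                     noise_sd = noise_sd_L, seed = sseed + 1L)
        fvc_vol <- simulate_maneuver("fvc", fvc = fvc_t, tau = tau,
                                     rate = config$sample_rate_spiro,
                                     noise_sd = noise_sd_L, seed = sseed + 2L)
        rip_svc <- render_rip_from_volume(svc_vol, gain, config$band_offset,
                                          sat_threshold_L, sat_gain,
                                          noise_sd = config$noise_sd,
                                          seed = sseed + 3L)
        rip_fvc <- render_rip_from_volume(fvc_vol, gain, config$band_offset,
                                          sat_threshold_L, sat_gain,
                                          noise_sd = config$noise_sd,
                                          seed = sseed + 4L)
        traces[[length(traces) + 1]] <- list(
          subject = sub, session = ses, trial = tr,
          spiro_svc = svc_vol, spiro_fvc = fvc_vol,
          rip_svc = rip_svc, rip_fvc = rip_fvc
        )
        rows[[length(rows) + 1]] <- tibble(subject = sub, session = ses,
                                           trial = tr, true_svc = svc_t,
                                           true_fvc = fvc_t)
      }
    }
  }
  list(traces = traces, truth = dplyr::bind_rows(rows))
}

analyse_maneuvers <- function(config, bank, sessions = c(1L, 2L), ...) {
  set <- simulate_maneuver_set(config, sessions = sessions, ...)
  rows <- list()
  for (tr in set$traces) {
    sitting <- tryCatch(bank_lookup(bank, tr$subject, "sitting"),
                        error = function(e) NULL)
    if (is.null(sitting)) next
    sp_svc <- as.numeric(extract_svc(tr$spiro_svc))
    sp_f <- extract_fvc_fev1(tr$spiro_fvc)
    rip_svc <- rip_maneuver_volumes(tr$rip_svc, sitting, "svc")$svc_L
    rip_f <- rip_maneuver_volumes(tr$rip_fvc, sitting, "fvc")
    rows[[length(rows) + 1]] <- tibble(
      subject = tr$subject, session = tr$session, trial = tr$trial,
      device = rep(c("spiro", "rip"), each = 3),
      parameter = rep(c("svc", "fvc", "fev1"), 2),
      value_L = c(sp_svc, sp_f$fvc, sp_f$fev1,
                  rip_svc, rip_f$fvc_L, rip_f$fev1_L)
    )
  }
  dplyr::bind_rows(rows)
}

#' Run the full validation pipeline
#'
#' End-to-end analysis of a two-session dataset: per-segment processing,
#' session-1 within-task self-calibration, session-2 calibration transfer
#' (session-1 models reapplied), per-subject Bland-Altman agreement of the
#' breath-averaged percentage differences, task-level aggregation against
#' the a priori criteria, the unmatchable-data exclusion log, and
#' (optionally) the maneuver analysis using each subject's sitting-task
#' calibration.
#'
#' @param x A [scenario_config()] (the dataset is simulated) or a
#'   [simulate_dataset()] / [load_dataset()] result.
#' @param params A [pipeline_params()] list.
#' @param sessions Sessions to analyse.
#' @param include_maneuvers Run the functional lung-volume analysis?
#' @param out_dir Optional directory; when given, the report tables are
#'   written as CSV plus a JSON run manifest.
#' @return A list of class `rip_report`: `task_summary` (one row per
#'   session x task), `subject_agreement` (long format), `bank`
#'   (calibration bank), `exclusions`, `maneuver_results`,
#'   `maneuver_agreement`, `maneuver_cov`, `params`, `config`.
#' @export
run_pipeline <- function(x, params = pipeline_params(), sessions = c(1L, 2L),
                         include_maneuvers = TRUE, out_dir = NULL) {
  dataset <- if (inherits(x, "rip_scenario")) {
    simulate_dataset(x, sessions = sessions)
  } else if (inherits(x, "rip_dataset")) {
    x
  } else {
    abort("`x` must be a scenario configuration or a dataset")
  }
  config <- dataset$config
  processed <- lapply(dataset$segments, function(seg) {
    tryCatch(process_segment(seg, params), error = function(e) {
      abort(sprintf("processing failed for subject %s session %s task '%s': %s",
                    seg$subject, seg$session, seg$task, conditionMessage(e)))
    })
  })
  is_ses <- function(p, s) p$session == s
  # session-1 self-calibration bank
  models <- list()
  missing <- list()
  for (p in processed) {
    if (!is_ses(p, 1L)) next
    if (p$match$excluded) {
      missing[[length(missing) + 1]] <- tibble(
        subject = p$subject, task = p$task,
        reason = sprintf("excluded in session 1 (unmatched %.0f%%)",
                         100 * p$match$unmatched_fraction))
      next
    }
    models[[length(models) + 1]] <-
      fit_calibration(p$tvs$rip_tv, p$tvs$spiro_tv, task = p$task,
                      subject = p$subject)
  }
  bank <- calibration_bank(models, dplyr::bind_rows(missing))
  # per-subject agreement, both sessions, using the session-1 models
  subj_rows <- list()
  excl_rows <- list()
  for (p in processed) {
    if (p$match$excluded) {
      excl_rows[[length(excl_rows) + 1]] <- tibble(
        subject = p$subject, session = p$session, task = p$task,
        unmatched_fraction = p$match$unmatched_fraction,
        reason = "more than 50% of breaths unmatchable")
      next
    }
    model <- tryCatch(bank_lookup(bank, p$subject, p$task),
                      error = function(e) NULL)
    if (is.null(model)) {
      excl_rows[[length(excl_rows) + 1]] <- tibble(
        subject = p$subject, session = p$session, task = p$task,
        unmatched_fraction = p$match$unmatched_fraction,
        reason = "no session-1 calibration available")
      next
    }
    tvs <- p$tvs
    tvs$rip_tv <- apply_calibration(model, tvs$rip_tv)
    ag <- tryCatch(subject_agreement(tvs, params$tv_window),
                   error = function(e) NULL)
    if (is.null(ag)) {
      excl_rows[[length(excl_rows) + 1]] <- tibble(
        subject = p$subject, session = p$session, task = p$task,
        unmatched_fraction = p$match$unmatched_fraction,
        reason = "too few matched breaths for the averaging window")
      next
    }
    subj_rows[[length(subj_rows) + 1]] <- dplyr::mutate(
      ag, subject = p$subject, session = p$session, task = p$task,
      lag_s = p$lag_s, .before = 1)
  }
  subject_agreement_tbl <- dplyr::bind_rows(subj_rows)
  exclusions <- dplyr::bind_rows(excl_rows)
  summarize_group <- function(df) {
    if (nrow(df) >= 2) {
      return(summarize_task(df, params$bias_limit, params$loa_limit))
    }
    tibble(central_bias = df$bias, central_loa = df$loa_halfwidth,
           n_subjects = 1L, meets_bias = abs(df$bias) < params$bias_limit,
           meets_loa = df$loa_halfwidth < params$loa_limit,
           central_stat = "single", normality_p = NA_real_,
           mean_bias = df$bias, median_bias = df$bias,
           mean_loa = df$loa_halfwidth, median_loa = df$loa_halfwidth)
  }
  task_summary <- if (nrow(subject_agreement_tbl)) {
    subject_agreement_tbl |>
      dplyr::group_by(.data$session, .data$task) |>
      dplyr::group_modify(~ summarize_group(.x)) |>
      dplyr::ungroup()
  } else {
    tibble(session = integer(0), task = character(0),
           central_bias = numeric(0), central_loa = numeric(0),
           n_subjects = integer(0), meets_bias = logical(0),
           meets_loa = logical(0), central_stat = character(0),
           normality_p = numeric(0), mean_bias = numeric(0),
           median_bias = numeric(0), mean_loa = numeric(0),
           median_loa = numeric(0))
  }
  maneuver_results <- NULL
  maneuver_agreement <- NULL
  maneuver_cov <- NULL
  if (include_maneuvers) {
    maneuver_results <- analyse_maneuvers(config, bank, sessions = sessions)
    if (nrow(maneuver_results)) {
      maneuver_agreement <- volume_agreement(maneuver_results)
      maneuver_cov <- maneuver_results |>
        dplyr::filter(.data$parameter %in% c("svc", "fvc")) |>
        dplyr::group_by(.data$subject, .data$session, .data$device,
                        .data$parameter) |>
        dplyr::summarise(cov = coefficient_of_variation(.data$value_L),
                         .groups = "drop")
    }
  }
  report <- structure(
    list(task_summary = task_summary,
         subject_agreement = subject_agreement_tbl,
         bank = bank, exclusions = exclusions,
         maneuver_results = maneuver_results,
         maneuver_agreement = maneuver_agreement,
         maneuver_cov = maneuver_cov,
         params = params, config = config),
    class = "rip_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.rip_report <- function(x, ...) {
  cat("<rip_report>\n")
  cat(sprintf("  %d task summaries, %d subject-task agreements, %d exclusions\n",
              nrow(x$task_summary), nrow(x$subject_agreement), nrow(x$exclusions)))
  if (!is.null(x$maneuver_agreement)) {
    cat(sprintf("  maneuver agreement rows: %d\n", nrow(x$maneuver_agreement)))
  }
  print(x$task_summary[, c("session", "task", "central_bias", "central_loa",
                           "meets_bias", "meets_loa")])
  invisible(x)
}

#' Exclusion log of a pipeline report
#'
#' One row per excluded (subject, session, task) with the unmatched breath
#' fraction and the reason.
#'
#' @param report A [run_pipeline()] result.
#' @return A tibble.
#' @export
exclusion_log <- function(report) {
  stopifnot(inherits(report, "rip_report"))
  report$exclusions
}

#' Write the report tables of a pipeline run
#'
#' Emits `task_summary.csv` (one row per session and task),
#' `subject_agreement.csv`, `calibration_bank.csv`, `exclusions.csv`,
#' maneuver tables when present, and `run_manifest.json` with the
#' parameters, configuration hash and seed.
#'
#' @param report A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "rip_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$task_summary, file.path(out_dir, "task_summary.csv"))
  readr::write_csv(report$subject_agreement,
                   file.path(out_dir, "subject_agreement.csv"))
  readr::write_csv(report$bank$table, file.path(out_dir, "calibration_bank.csv"))
  readr::write_csv(report$exclusions, file.path(out_dir, "exclusions.csv"))
  if (!is.null(report$maneuver_agreement)) {
    readr::write_csv(report$maneuver_agreement,
                     file.path(out_dir, "maneuver_agreement.csv"))
    readr::write_csv(report$maneuver_results,
                     file.path(out_dir, "maneuver_results.csv"))
  }
  manifest <- list(package = "ripvol",
                   seed = report$config$seed,
                   config_hash = rlang::hash(unclass(report$config)),
                   params = unclass(report$params))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
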