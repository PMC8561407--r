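#' Write a signal trace to a two-column CSV
#'
#' @param trace A [signal_trace()].
#' @param path Output file; columns `time_s,value`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is_trace(trace))
  # full 17-significant-digit formatting so doubles round-trip bit-exactly
  lines <- c("time_s,value",
             sprintf("%.17g,%.17g", trace_times(trace), trace$samples))
  writeLines(lines, path)
  invisible(path)
}

#' Read a signal trace from a two-column CSV
#'
#' Expects a `time_s,value` header and strictly increasing times. A file
#' whose sampling is irregular (relative step spread > 1e-6) is linearly
#' resampled onto the median rate and flagged via the `resampled` attribute.
#'
#' @param path CSV file path.
#' @param expected_unit Unit label to attach to the trace.
#' @param channel Channel label (defaults to the file name stem).
#' @return A [signal_trace()]; attribute `resampled` is `TRUE` when the
#'   input was irregular.
#' @export
read_trace <- function(path, expected_unit = "a.u.", channel = NULL) {
  if (!file.exists(path)) abort(sprintf("trace file not found: %s", path))
  # base read.csv parses doubles with correctly rounded strtod, so traces
  # written by write_trace() round-trip bit-exactly
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    abort(sprintf("%s: expected header 'time_s,value'", path))
  }
  df$time_s <- as.numeric(df$time_s)
  df$value <- as.numeric(df$value)
  if (anyNA(df$time_s) || anyNA(df$value)) {
    bad <- which(is.na(df$time_s) | is.na(df$value))[1]
    abort(sprintf("%s: NaN/missing sample at row %d", path, bad))
  }
  if (is.null(channel)) channel <- sub("\\.csv$", "", basename(path))
  if (nrow(df) < 2) {
    return(signal_trace(df$value, rate = 1, unit = expected_unit,
                        channel = channel, t0 = if (nrow(df)) df$time_s[1] else 0))
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1
    abort(sprintf("%s: non-monotone time at row %d", path, bad))
  }
  step <- median(dt)
  irregular <- (max(dt) - min(dt)) / step > 1e-6
  if (irregular) {
    grid <- seq(df$time_s[1], df$time_s[nrow(df)], by = step)
    y <- approx(df$time_s, df$value, xout = grid)$y
    out <- signal_trace(y, 1 / step, expected_unit, channel, t0 = df$time_s[1])
  } else {
    out <- signal_trace(df$value, 1 / step, expected_unit, channel,
                        t0 = df$time_s[1])
  }
  attr(out, "resampled") <- irregular
  out
}

seg_dir <- function(root, subject, session) {
  file.path(root, sprintf("sub%d", subject), sprintf("ses%d", session))
}

#' Write a simulated dataset to disk
#'
#' Layout: `<root>/manifest.json` plus, per segment,
#' `sub<k>/ses<s>/<task>_{thoracic,abdominal,spiro}.csv` (`time_s,value`)
#' and `sub<k>/ses<s>/<task>_truth.csv`
#' (`breath_index,t_start_s,tv_L`). The manifest records the scenario
#' configuration, seed and every file written.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param root Output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_dataset <- function(dataset, root) {
  stopifnot(inherits(dataset, "rip_dataset"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (seg in dataset$segments) {
    d <- seg_dir(root, seg$subject, seg$session)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    paths <- c(thoracic = file.path(d, paste0(seg$task, "_thoracic.csv")),
               abdominal = file.path(d, paste0(seg$task, "_abdominal.csv")),
               spiro = file.path(d, paste0(seg$task, "_spiro.csv")))
    write_trace(seg$thoracic, paths[["thoracic"]])
    write_trace(seg$abdominal, paths[["abdominal"]])
    write_trace(seg$spiro_flow, paths[["spiro"]])
    truth_path <- file.path(d, paste0(seg$task, "_truth.csv"))
    readr::write_csv(seg$truth[, c("breath_index", "t_start_s", "tv_L")],
                     truth_path)
    files[[length(files) + 1]] <- tibble(
      subject = seg$subject, session = seg$session, task = seg$task,
      thoracic = paths[["thoracic"]], abdominal = paths[["abdominal"]],
      spiro = paths[["spiro"]], truth = truth_path
    )
  }
  file_map <- if (length(files)) dplyr::bind_rows(files) else
    tibble(subject = integer(0), session = integer(0), task = character(0),
           thoracic = character(0), abdominal = character(0),
           spiro = character(0), truth = character(0))
  rel <- function(p) sub(paste0("^", root, "/?"), "", p)
  manifest <- list(
    package = "ripvol",
    seed = dataset$config$seed,
    config = unclass(dataset$config),
    subjects = sort(unique(file_map$subject)),
    sessions = sort(unique(file_map$session)),
    tasks = unique(file_map$task),
    config_hash = rlang::hash(unclass(dataset$config)),
    segments = dplyr::mutate(file_map, dplyr::across(
      c("thoracic", "abdominal", "spiro", "truth"), rel))
  )
  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(root)
}

#' Load a dataset written by [write_dataset()]
#'
#' Validates that every file named by the manifest exists, then rebuilds the
#' segment list (thoracic, abdominal, spirometer flow and ground truth per
#' subject/session/task).
#'
#' @param root Dataset directory containing `manifest.json`.
#' @return An object of class `rip_dataset` (the `config` element is the
#'   manifest's stored configuration, reconstructed).
#' @export
load_dataset <- function(root) {
  mp <- file.path(root, "manifest.json")
  if (!file.exists(mp)) abort(sprintf("no manifest.json under %s", root))
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  segs <- man$segments
  cfg_l <- man$config
  cfg <- scenario_config(
    n_subjects = cfg_l$n_subjects, tasks = as_tibble(cfg_l$tasks),
    task_duration = cfg_l$task_duration,
    thoracic_fraction = cfg_l$thoracic_fraction,
    band_gain_thoracic = cfg_l$band_gain_thoracic,
    band_gain_abdominal = cfg_l$band_gain_abdominal,
    band_offset = cfg_l$band_offset, subject_gain_sd = cfg_l$subject_gain_sd,
    amp_jitter_sd = cfg_l$amp_jitter_sd,
    session2_gain_multiplier = cfg_l$session2_gain_multiplier,
    session2_offset_delta = cfg_l$session2_offset_delta,
    drift_rate = cfg_l$drift_rate, noise_sd = cfg_l$noise_sd,
    artefact_amplitude = cfg_l$artefact_amplitude,
    artefact_duration_s = cfg_l$artefact_duration_s,
    device_lag = cfg_l$device_lag, sample_rate_rip = cfg_l$sample_rate_rip,
    sample_rate_spiro = cfg_l$sample_rate_spiro, seed = cfg_l$seed
  )
  if (is.null(segs) || !NROW(segs)) {
    return(structure(list(config = cfg, segments = list(),
                          truth = tibble(), meta = tibble()),
                     class = "rip_dataset"))
  }
  segments <- vector("list", nrow(segs))
  truth_rows <- vector("list", nrow(segs))
  meta_rows <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    row <- segs[i, ]
    for (col in c("thoracic", "abdominal", "spiro", "truth")) {
      p <- file.path(root, row[[col]])
      if (!file.exists(p)) abort(sprintf("manifest names missing file: %s", p))
    }
    truth <- readr::read_csv(file.path(root, row$truth),
                             col_types = readr::cols())
    segments[[i]] <- structure(
      list(subject = row$subject, session = row$session, task = row$task,
           thoracic = read_trace(file.path(root, row$thoracic), "a.u.", "thoracic"),
           abdominal = read_trace(file.path(root, row$abdominal), "a.u.", "abdominal"),
           spiro_flow = read_trace(file.path(root, row$spiro), "L/s", "spiro_flow"),
           truth = truth, artefacts = NULL,
           gain_effective = NA_real_, gain_factor = NA_real_,
           device_lag = cfg$device_lag),
      class = "rip_segment")
    truth_rows[[i]] <- dplyr::mutate(truth, subject = row$subject,
                                     session = row$session, task = row$task,
                                     .before = 1)
    meta_rows[[i]] <- tibble(subject = row$subject, session = row$session,
                             task = row$task, n_breaths = nrow(truth),
                             gain_effective = NA_real_,
                             device_lag_s = cfg$device_lag, n_artefacts = NA_integer_)
  }
  structure(list(config = cfg, segments = segments,
                 truth = dplyr::bind_rows(truth_rows),
                 meta = dplyr::bind_rows(meta_rows)),
            class = "rip_dataset")
}
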