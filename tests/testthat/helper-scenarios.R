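# Shared scenario builders. Small durations keep the suite fast; the
# study-scale conditions live in the acceptance tests.

lying_task <- function(artefact_rate = 0) {
  tt <- default_task_table()[1, ]
  tt$artefact_rate <- artefact_rate
  tt
}

# noise-free, drift-free, artefact-free scenario (known-truth recovery tests)
clean_scenario <- function(tasks = lying_task(), n_subjects = 1,
                           task_duration = 60, seed = 1, ...) {
  scenario_config(n_subjects = n_subjects, tasks = tasks,
                  task_duration = task_duration, noise_sd = 0,
                  amp_jitter_sd = 0, drift_rate = 0, subject_gain_sd = 0,
                  artefact_amplitude = 0, seed = seed, ...)
}

# realistic noise (defaults), small size
noisy_scenario <- function(tasks = lying_task(), n_subjects = 2,
                           task_duration = 90, seed = 1, ...) {
  scenario_config(n_subjects = n_subjects, tasks = tasks,
                  task_duration = task_duration, seed = seed, ...)
}

# a perfectly clean single-breath truth table
one_breath_truth <- function(tv = 1.0, duration = 4) {
  tibble::tibble(breath_index = 1L, t_start_s = 1, duration_s = duration,
                 t_insp_end_s = 1 + duration / 2.5, tv_L = tv)
}
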