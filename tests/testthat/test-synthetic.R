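test_that("breath trains follow the task distributions and cover the task", {
  cfg <- scenario_config(n_subjects = 1, task_duration = 1200)
  tr <- generate_breath_train(cfg, "bend_over_sitting", subject_seed = 123)
  # defaults anchored at 0.67 (SD 0.14) L; long train recovers the mean
  expect_lt(abs(mean(tr$tv_L) - 0.67), 3 * 0.14 / sqrt(nrow(tr)) + 0.01)
  expect_true(all(diff(tr$t_start_s) > 0))
  expect_true(all(tr$tv_L > 0.05))
  expect_true(all(tr$duration_s > 1))
  expect_gte(max(tr$t_start_s + tr$duration_s), cfg$task_duration)
})

test_that("degenerate distributions give identical breaths", {
  tt <- lying_task()
  tt$tv_sd <- 0
  tt$rr_sd <- 0
  cfg <- scenario_config(n_subjects = 1, tasks = tt, task_duration = 60)
  tr <- generate_breath_train(cfg, "lying", subject_seed = 1)
  expect_equal(length(unique(tr$tv_L)), 1)
  expect_equal(length(unique(round(tr$duration_s, 12))), 1)
})

test_that("breath trains are deterministic under a fixed seed", {
  cfg <- scenario_config(n_subjects = 1, task_duration = 60)
  a <- generate_breath_train(cfg, "lying", subject_seed = 7)
  b <- generate_breath_train(cfg, "lying", subject_seed = 7)
  expect_identical(a, b)
})

test_that("unknown task labels raise a configuration error", {
  cfg <- scenario_config(n_subjects = 1)
  expect_error(generate_breath_train(cfg, "jogging", 1), "unknown task")
  expect_error(simulate_segment(cfg, 1, 1, "jogging"), "unknown task")
})

test_that("spirometer inspiratory lobes integrate to the true tidal volume", {
  # single constructed breath: trapezoidal quadrature of the inspiratory lobe
  truth <- one_breath_truth(tv = 1.0, duration = 4)
  tr <- render_spirometer_trace(truth, rate = 100)
  tt <- trace_times(tr)
  insp <- tt >= 1 & tt <= 1 + 4 / 2.5
  got <- pracma::trapz(tt[insp], pmax(tr$samples[insp], 0))
  expect_lt(abs(got - 1.0), 0.005)

  # full lying train: every inspiratory integral within 0.5 % of truth
  cfg <- clean_scenario(task_duration = 300)
  train <- generate_breath_train(cfg, "lying", subject_seed = 5)
  tr <- render_spirometer_trace(train, rate = 100)
  tt <- trace_times(tr)
  flow_pos <- pmax(tr$samples, 0)
  per_breath <- vapply(seq_len(nrow(train)), function(k) {
    sel <- tt >= train$t_start_s[k] & tt <= train$t_start_s[k] + train$duration_s[k]
    pracma::trapz(tt[sel], flow_pos[sel])
  }, numeric(1))
  expect_true(all(abs(per_breath / train$tv_L - 1) < 0.005))
  # zero net volume drift over the task
  expect_lt(abs(pracma::trapz(tt, tr$samples)), 0.01)
})

test_that("empty truth renders a zero-length spirometer trace", {
  empty <- generate_breath_train(scenario_config(n_subjects = 1), "lying", 1)[0, ]
  tr <- render_spirometer_trace(empty, rate = 100)
  expect_equal(length(tr$samples), 0)
})

test_that("noiseless RIP band sum is an exact affine function of TV", {
  truth <- one_breath_truth(tv = 1.0, duration = 4)
  cfg <- clean_scenario(device_lag = 0)
  rip <- render_rip_traces(truth, cfg, session = 1)
  summed <- rip$thoracic$samples + rip$abdominal$samples
  # gains (2, 1), thoracic fraction 0.6: amplitude = 0.6*2 + 0.4*1 = 1.6 a.u.
  # (tolerance covers peak-sampling quantisation at 128 Hz)
  expect_equal(max(summed) - min(summed), 1.6, tolerance = 1e-4)
  expect_equal(rip$gain_effective, 1.6)

  # affine in TV: residuals of a straight-line fit are at machine precision
  tvs <- c(0.4, 0.8, 1.2, 1.6)
  amps <- vapply(tvs, function(v) {
    r <- render_rip_traces(one_breath_truth(tv = v), cfg, session = 1)
    s <- r$thoracic$samples + r$abdominal$samples
    max(s) - min(s)
  }, numeric(1))
  fit <- lm(amps ~ tvs)
  expect_lt(max(abs(residuals(fit))), 1e-9)
})

test_that("session 2 reuses session 1 statistics when the multiplier is 1", {
  truth <- one_breath_truth()
  cfg <- clean_scenario(session2_gain_multiplier = 1.0)
  r1 <- render_rip_traces(truth, cfg, session = 1, seed = 11)
  r2 <- render_rip_traces(truth, cfg, session = 2, seed = 11)
  expect_identical(r1$thoracic$samples, r2$thoracic$samples)

  cfg2 <- clean_scenario(session2_gain_multiplier = 1.1)
  r2b <- render_rip_traces(truth, cfg2, session = 2, seed = 11)
  amp1 <- max(r1$thoracic$samples) - min(r1$thoracic$samples)
  amp2 <- max(r2b$thoracic$samples) - min(r2b$thoracic$samples)
  expect_equal(amp2 / amp1, 1.1, tolerance = 1e-9)
})

test_that("datasets are deterministic under a fixed master seed", {
  cfg <- noisy_scenario(n_subjects = 1, task_duration = 40)
  a <- simulate_dataset(cfg, sessions = 1L)
  b <- simulate_dataset(cfg, sessions = 1L)
  expect_identical(a$truth, b$truth)
  expect_identical(a$segments[[1]]$thoracic$samples,
                   b$segments[[1]]$thoracic$samples)
})

test_that("scenario validation rejects out-of-range parameters", {
  expect_error(scenario_config(thoracic_fraction = 1.2), "thoracic_fraction")
  tt <- lying_task()
  tt$tv_mean <- -1
  expect_error(scenario_config(tasks = tt), "tv_mean")
})
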