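test_that("Savitzky-Golay smoothing preserves low-order polynomials", {
  t <- seq(0, 10, by = 0.01)
  quad <- signal_trace(2 + 3 * t - 0.5 * t^2, rate = 100)
  sm <- savgol_smooth(quad, window_s = 0.75, polyorder = 3)
  interior <- 200:800
  expect_lt(max(abs(sm$samples[interior] - quad$samples[interior])), 1e-9)
  expect_equal(length(sm$samples), length(quad$samples))
  expect_equal(sm$rate, quad$rate)
})

test_that("smoothing reduces noise variance and RMS error", {
  withr::local_seed(42)
  t <- seq(0, 20, by = 0.01)
  noise <- rnorm(length(t), 0, 0.3)
  noisy <- signal_trace(noise, rate = 100)
  sm <- savgol_smooth(noisy)
  expect_lt(var(sm$samples), var(noisy$samples))

  clean <- sin(2 * pi * 0.25 * t)
  contaminated <- signal_trace(clean + 0.2 * sin(2 * pi * 20 * t) + noise * 0.1,
                               rate = 100)
  sm2 <- savgol_smooth(contaminated)
  rms_before <- sqrt(mean((contaminated$samples - clean)^2))
  rms_after <- sqrt(mean((sm2$samples - clean)^2))
  expect_lt(rms_after, rms_before)
})

test_that("too-short smoothing windows are rejected", {
  tr <- signal_trace(rnorm(100), rate = 4)
  expect_error(savgol_smooth(tr, window_s = 0.5, polyorder = 3), "too short")
})

test_that("band summation adds samples over the common support", {
  a <- signal_trace(rep(2, 100), rate = 10)
  b <- signal_trace(rep(3, 100), rate = 10)
  expect_equal(unique(sum_bands(a, b)$samples), 5)

  z <- signal_trace(rep(0, 100), rate = 10)
  th <- signal_trace(sin(1:100 / 5), rate = 10)
  expect_equal(sum_bands(th, z)$samples, th$samples, tolerance = 1e-12)

  expect_error(sum_bands(a, signal_trace(1:10, 10, t0 = 100)), "no overlapping")
})

test_that("flow integrates to analytic volumes", {
  const <- signal_trace(rep(1, 201), rate = 100, unit = "L/s")
  vol <- integrate_flow(const, detrend = FALSE)
  expect_equal(vol$samples[201], 2.0, tolerance = 1e-9)
  expect_equal(vol$unit, "L")

  t <- seq(0, 10, by = 0.01)
  sine <- signal_trace(sin(2 * pi * 0.5 * t), rate = 100, unit = "L/s")
  v <- integrate_flow(sine, detrend = FALSE)$samples
  at_periods <- v[seq(1, length(t), by = 200)]
  expect_lt(max(abs(at_periods)), 1e-4)
})

test_that("integration is exactly linear in the flow", {
  withr::local_seed(1)
  f <- signal_trace(rnorm(500), rate = 50, unit = "L/s")
  f3 <- signal_trace(3 * f$samples, rate = 50, unit = "L/s")
  expect_equal(integrate_flow(f3)$samples, 3 * integrate_flow(f)$samples,
               tolerance = 1e-12)
})

test_that("detrended integration absorbs a small sensor offset", {
  cfg <- clean_scenario(task_duration = 120, device_lag = 0)
  seg <- simulate_segment(cfg, 1, 1, "lying")
  biased <- signal_trace(seg$spiro_flow$samples + 0.002, seg$spiro_flow$rate,
                         "L/s", "spiro_flow")
  vol <- integrate_flow(biased, detrend = TRUE)
  breaths <- detect_breaths(vol)
  expect_equal(nrow(breaths), nrow(seg$truth))
  expect_true(all(abs(breaths$tv / seg$truth$tv_L - 1) < 0.01))
})

test_that("lag estimation recovers constructed and simulated lags", {
  t <- seq(0, 40, by = 0.01)
  x <- sin(2 * pi * 0.25 * t) + 0.3 * sin(2 * pi * 0.11 * t)
  tr <- signal_trace(x, 100, "L")
  expect_equal(estimate_lag(tr, tr), 0)
  shifted <- signal_trace(x, 100, "L", t0 = 1.25)
  expect_lt(abs(estimate_lag(shifted, tr) - 1.25), 0.01 + 1e-9)

  cfg <- noisy_scenario(task_duration = 60, device_lag = 0.8)
  seg <- simulate_segment(cfg, 1, 1, "lying")
  rip <- sum_bands(savgol_smooth(seg$thoracic), savgol_smooth(seg$abdominal))
  vol <- integrate_flow(seg$spiro_flow)
  expect_lt(abs(estimate_lag(rip, vol) - 0.8), 0.01 + 1e-9)

  flat <- signal_trace(rep(1, 2000), 100, "L")
  expect_error(estimate_lag(flat, flat), "zero-variance")
  short <- signal_trace(sin(1:100), 100, "L")
  expect_error(estimate_lag(short, tr), "10 s")
})

test_that("alignment crops, shares a rate and is idempotent", {
  t <- seq(0, 40, by = 0.01)
  x <- sin(2 * pi * 0.25 * t) + 0.3 * sin(2 * pi * 0.11 * t)
  a <- signal_trace(x, 100, "a.u.")
  b <- signal_trace(x, 100, "L")
  al0 <- align_traces(a, b, 0)
  expect_equal(al0$rip_volume_raw$samples, al0$spiro_volume$samples)

  shifted <- signal_trace(x, 100, "a.u.", t0 = 1.25)
  lag <- estimate_lag(shifted, b)
  al <- align_traces(shifted, b, lag)
  residual <- estimate_lag(al$rip_volume_raw, al$spiro_volume)
  expect_lt(abs(residual), 0.01 + 1e-9)

  hi <- signal_trace(approx(t, x, xout = seq(0, 40, by = 1 / 128))$y, 128, "a.u.")
  al2 <- align_traces(hi, b, 0)
  expect_equal(al2$rate, 100)
  expect_equal(length(al2$rip_volume_raw$samples),
               length(al2$spiro_volume$samples))
})
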