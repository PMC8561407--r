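test_that("SVC is the total maneuver excursion", {
  up <- seq(0, 5, by = 0.01)
  ramp <- signal_trace(c(up, rev(up)), 100, "L")
  expect_equal(as.numeric(extract_svc(ramp)), 5.0, tolerance = 0.01)

  flat <- signal_trace(rep(2, 500), 100, "L")
  expect_warning(res <- extract_svc(flat), "invalid")
  expect_false(attr(res, "valid"))
  expect_equal(as.numeric(res), 0)

  sv <- simulate_maneuver("svc", svc = 4.2, noise_sd = 0.042, seed = 9)
  expect_lt(abs(as.numeric(extract_svc(sv)) - 4.2), 0.09 + 0.05)
})

test_that("FEV1 matches the exponential-expiration closed form", {
  tr <- simulate_maneuver("fvc", fvc = 4, tau = 0.5)
  res <- extract_fvc_fev1(tr)
  expect_lt(abs(res$fvc - 4) / 4, 0.005)
  expect_lt(abs(res$fev1 - 4 * (1 - exp(-2))) / (4 * (1 - exp(-2))), 0.005)
})

test_that("instant and linear emptying give FEV1 equal to FVC", {
  fast <- extract_fvc_fev1(simulate_maneuver("fvc", fvc = 4, tau = 0.02))
  expect_equal(fast$fev1, fast$fvc, tolerance = 0.01)

  # linear emptying of 3 L in exactly 1 s
  rate <- 100
  x <- c(rep(0, 100), seq(0, 3, length.out = 100), rep(3, 50),
         seq(3, 0, length.out = 101), rep(0, 100))
  lin <- extract_fvc_fev1(signal_trace(x, rate, "L"))
  expect_equal(lin$fvc, 3.0, tolerance = 0.05)
  expect_equal(lin$fev1, lin$fvc, tolerance = 0.1)
})

test_that("fev1 never exceeds fvc across random maneuvers", {
  for (k in 1:10) {
    tr <- simulate_maneuver("fvc", fvc = runif(1, 2, 6), tau = runif(1, 0.2, 1),
                            noise_sd = 0.02, seed = k)
    res <- extract_fvc_fev1(tr)
    expect_lte(res$fev1, res$fvc)
    expect_gt(res$fev1, 0)
  }
})

test_that("a slow descent is not accepted as a forced expiration", {
  t <- seq(0, 20, by = 0.01)
  slow <- signal_trace(3 - 0.15 * t, 100, "L")
  expect_error(extract_fvc_fev1(slow), "no forced expiration")
})

test_that("noise-free synthetic maneuvers are recovered within 0.5%", {
  sv <- simulate_maneuver("svc", svc = 4.2)
  expect_lt(abs(as.numeric(extract_svc(sv)) - 4.2) / 4.2, 0.005)
  fv <- simulate_maneuver("fvc", fvc = 3.5, tau = 0.4)
  res <- extract_fvc_fev1(fv)
  expect_lt(abs(res$fvc - 3.5) / 3.5, 0.005)
  expect_lt(abs(res$fev1 - 3.5 * (1 - exp(-1 / 0.4))) / 3.5, 0.005)
})

test_that("calibrated RIP reproduces maneuvers in the linear regime only", {
  model <- fit_calibration(c(1.6, 3.2, 4.8), c(1, 2, 3) * 1.6 / 1.6)
  model$a <- 1 / 1.6
  model$b <- 0
  vol <- simulate_maneuver("svc", svc = 4.2)
  rip_lin <- render_rip_from_volume(vol, gain = 1.6, offset = 5)
  got <- rip_maneuver_volumes(rip_lin, model, "svc")$svc_L
  expect_lt(abs(got - 4.2) / 4.2, 0.01)

  # saturating belt response underestimates large excursions
  rip_sat <- render_rip_from_volume(vol, gain = 1.6, offset = 5,
                                    sat_threshold_L = 2, sat_gain = 0.5)
  got_sat <- rip_maneuver_volumes(rip_sat, model, "svc")$svc_L
  expect_lt(got_sat, 4.2 - 0.5)

  expect_error(rip_maneuver_volumes(rip_lin, list(a = 1), "svc"),
               "calibration model")
})

test_that("saturation makes the volume error grow with the true volume", {
  model <- structure(list(a = 1 / 1.6, b = 0), class = "rip_calibration")
  errs <- vapply(c(3, 4, 5), function(v) {
    vol <- simulate_maneuver("svc", svc = v)
    rip <- render_rip_from_volume(vol, gain = 1.6, offset = 5,
                                  sat_threshold_L = 2, sat_gain = 0.5)
    v - rip_maneuver_volumes(rip, model, "svc")$svc_L
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("pooled volume agreement matches hand computation", {
  mk <- function(vals, device) {
    tibble::tibble(subject = seq_along(vals), session = 1, trial = 1,
                   device = device, parameter = "svc", value_L = vals)
  }
  same <- dplyr::bind_rows(mk(c(4, 5, 6), "spiro"), mk(c(4, 5, 6), "rip"))
  va <- volume_agreement(same)
  expect_equal(va$bias_L, 0)
  expect_equal(va$loa_halfwidth_L, 0)
  expect_true(va$meets_loa)

  # differences 0.2, 0.4, 0.6 L: bias 0.4, LOA 1.96 * 0.2 = 0.392, fails
  off <- dplyr::bind_rows(mk(c(4, 5, 6), "spiro"),
                          mk(c(4, 5, 6) - c(0.2, 0.4, 0.6), "rip"))
  va2 <- volume_agreement(off)
  expect_equal(va2$bias_L, 0.4)
  expect_equal(va2$loa_halfwidth_L, 0.392)
  expect_false(va2$meets_loa)
})
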