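test_that("a pure sinusoid yields one breath per cycle at full amplitude", {
  t <- seq(0, 60, by = 0.01)
  x <- -cos(2 * pi * (12 / 60) * t)  # 12 breaths/min, starts at a trough
  breaths <- detect_breaths(signal_trace(x, 100, "L"))
  expect_equal(nrow(breaths), 12)
  expect_true(all(abs(breaths$tv - 2) < 1e-3))
  expect_true(all(breaths$t_end_exp < breaths$t_end_insp))
})

test_that("a constant trace has no breaths", {
  tr <- signal_trace(rep(1, 1000), 100, "L")
  expect_equal(nrow(detect_breaths(tr)), 0)
})

test_that("detected breaths alternate strictly in time", {
  cfg <- noisy_scenario(task_duration = 90)
  seg <- simulate_segment(cfg, 1, 1, "lying")
  p <- process_segment(seg)
  for (b in list(p$spiro_breaths, p$rip_breaths)) {
    expect_true(all(b$t_end_exp < b$t_end_insp))
    expect_true(all(head(b$t_end_insp, -1) < tail(b$t_end_exp, -1)))
    expect_true(all(b$tv > 0))
  }
})

test_that("clean simulations recover the true breath count and volumes", {
  cfg <- clean_scenario(task_duration = 120)
  seg <- simulate_segment(cfg, 1, 1, "lying")
  p <- process_segment(seg)
  expect_equal(nrow(p$spiro_breaths), nrow(seg$truth))
  expect_equal(nrow(p$rip_breaths), nrow(seg$truth))
  expect_true(all(abs(p$spiro_breaths$tv / seg$truth$tv_L - 1) < 0.01))
  rip_expected <- seg$gain_effective * seg$truth$tv_L
  expect_true(all(abs(p$rip_breaths$tv / rip_expected - 1) < 0.01))
})

test_that("small spurious excursions are pruned by the prominence rule", {
  t <- seq(0, 60, by = 0.01)
  x <- -cos(2 * pi * 0.2 * t) + 0.05 * sin(2 * pi * 2.1 * t)
  breaths <- detect_breaths(signal_trace(x, 100, "L"))
  expect_equal(nrow(breaths), 12)
})

test_that("breath matching is one-to-one with the 50% exclusion rule", {
  mk <- function(times) {
    tibble::tibble(breath_index = seq_along(times), t_end_exp = times - 1,
                   t_end_insp = times, level_end_exp = 0, level_end_insp = 1,
                   tv = 1)
  }
  a <- mk(seq(2, 20, by = 2))
  m <- match_breaths(a, a, tol_s = 0.5)
  expect_equal(nrow(m$pairs), 10)
  expect_equal(m$unmatched_fraction, 0)
  expect_false(m$excluded)

  # 6 of 10 displaced beyond tolerance: 4 pairs, 60% unmatched, excluded
  b <- mk(c(seq(2, 8, by = 2), seq(10, 20, by = 2) + 0.9))
  m2 <- match_breaths(a, b, tol_s = 0.5)
  expect_equal(nrow(m2$pairs), 4)
  expect_equal(m2$unmatched_fraction, 0.6)
  expect_true(m2$excluded)

  # 4 displaced: 40% unmatched, retained
  b3 <- mk(c(seq(2, 12, by = 2), seq(14, 20, by = 2) + 0.9))
  m3 <- match_breaths(a, b3, tol_s = 0.5)
  expect_equal(m3$unmatched_fraction, 0.4)
  expect_false(m3$excluded)
})

test_that("tv_series refuses excluded tasks and orders pairs by time", {
  mk <- function(times) {
    tibble::tibble(breath_index = seq_along(times), t_end_exp = times - 1,
                   t_end_insp = times, level_end_exp = 0, level_end_insp = 1,
                   tv = seq_along(times))
  }
  a <- mk(seq(2, 20, by = 2))
  m <- match_breaths(a, a, tol_s = 0.5)
  tvs <- tv_series(m)
  expect_equal(nrow(tvs), 10)
  expect_true(!is.unsorted(tvs$t_s))

  b <- mk(c(seq(2, 8, by = 2), seq(10, 20, by = 2) + 0.9))
  m2 <- match_breaths(a, b, tol_s = 0.5)
  expect_error(tv_series(m2), "task excluded \\(unmatched 60%\\)")
})

test_that("heavy artefacts push tasks over the exclusion threshold", {
  cfg <- scenario_config(n_subjects = 1, tasks = lying_task(artefact_rate = 15),
                         task_duration = 120, artefact_amplitude = 8,
                         artefact_duration_s = 4, seed = 3)
  p <- process_segment(simulate_segment(cfg, 1, 1, "lying"))
  expect_true(p$match$excluded)
  expect_gt(p$match$unmatched_fraction, 0.5)
})

test_that("raising the artefact rate never lowers mean unmatched fraction", {
  mean_uf <- function(rate) {
    uf <- vapply(1:4, function(k) {
      cfg <- scenario_config(n_subjects = 1,
                             tasks = lying_task(artefact_rate = rate),
                             task_duration = 90, artefact_amplitude = 8,
                             artefact_duration_s = 4, seed = 40 + k)
      process_segment(simulate_segment(cfg, 1, 1, "lying"))$match$unmatched_fraction
    }, numeric(1))
    mean(uf)
  }
  ufs <- vapply(c(0, 6, 15), mean_uf, numeric(1))
  expect_true(all(diff(ufs) >= 0))
})
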