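# ripvol

Respiratory inductance plethysmography (RIP) garments — smart shirts with a
thoracic and an abdominal inductance band — promise continuous, unobtrusive
monitoring of breathing. Before such a garment can be trusted for
telemonitoring, its tidal-volume (TV) readout must be validated against a
reference spirometer: calibrated per task, compared breath by breath, and
judged against a priori accuracy criteria. `ripvol` implements that whole
validation pipeline for R users working on wearable-sensor method
comparison, together with a synthetic dual-device data generator with known
ground truth, so every stage of the chain can be exercised and stress-tested
without access to raw subject data.

## The method

For each subject and task, the two RIP band signals are Savitzky–Golay
smoothed and summed into one volume-proportional signal (arbitrary units);
the spirometer flow is integrated to volume (L); the inter-device delay is
removed by normalized cross-correlation; end-expiratory troughs and
end-inspiratory peaks delimit breaths, whose tidal volume is the
peak-to-trough level difference. Breaths are paired across devices by
nearest end-inspiration time; a task in which more than 50 % of breaths are
unmatchable is excluded.

Matched tidal volumes calibrate the garment by ordinary least squares,

    TV_L = a · TV_raw + b,

fitted per subject and task in session 1 (the calibration factors *a*, *b*).
The same session-1 factors are reapplied to session 2, in which the garment
has been taken off and put back on, to test calibration transfer. After a
5-breath centered moving average on both devices' calibrated series, the
inter-device difference is expressed as a percentage of the reference,

    diffTV = 100 · (TV_SPIRO − TV_HX) / TV_SPIRO,

so that overestimation by the garment is negative. Per subject and task a
Bland–Altman analysis gives the bias (mean diffTV) and limits of agreement
(LOA, the half-width 1.96 · SD). Across subjects the central bias and LOA
(mean if the per-subject biases pass a Shapiro–Wilk test at α = 0.05,
median otherwise) are checked against the a priori criteria |bias| < 5 %
and LOA < 15 %. A separate maneuver module extracts SVC, FVC and FEV₁ from
slow and forced vital-capacity recordings (forced-expiration start by
ATS/ERS-style back-extrapolation), calibrates the garment trace with the
subject's sitting-task factors, and checks the volume criterion
LOA ≤ 0.150 L.

## Worked example

```r
library(ripvol)

cfg <- scenario_config(n_subjects = 5, task_duration = 300,
                       tasks = default_task_table()[c(1, 2), ], seed = 2024)
report <- run_pipeline(cfg, include_maneuvers = TRUE)
report$task_summary[, c("session", "task", "central_bias", "central_loa",
                        "n_subjects", "meets_bias", "meets_loa")]
#> # A tibble: 4 × 7
#>   session task    central_bias central_loa n_subjects meets_bias meets_loa
#>     <int> <chr>          <dbl>       <dbl>      <int> <lgl>      <lgl>
#> 1       1 lying       -0.0312         2.83          5 TRUE       TRUE
#> 2       1 sitting      0.00551        2.48          5 TRUE       TRUE
#> 3       2 lying      -10.1            3.12          5 FALSE      TRUE
#> 4       2 sitting     -9.50           2.76          5 FALSE      TRUE
```

Session 1 self-calibrates, so its biases sit at a fraction of a percent and
both criteria pass. In session 2 the simulated garment reapplication has
multiplied both band gains by 1.1 (the default
`session2_gain_multiplier`); reusing the session-1 factors then biases the
garment TV by about 100 · (1 − 1.1) ≈ −10 % while the LOA stay narrow:
an accuracy problem, not a precision problem.

```r
report$maneuver_agreement
#> # A tibble: 6 × 6
#>   session parameter bias_L loa_halfwidth_L     n meets_loa
#>     <int> <chr>      <dbl>           <dbl> <int> <lgl>
#> 1       1 fev1       0.993           0.408    15 FALSE
#> 2       1 fvc        1.11            0.430    15 FALSE
#> 3       1 svc        1.25            0.159    15 FALSE
#> 4       2 fev1       0.882           1.19     15 FALSE
#> 5       2 fvc        0.942           1.36     15 FALSE
#> 6       2 svc        0.939           0.163    15 FALSE
```

The simulated belts respond sub-linearly above the tidal range used for
calibration, so maneuver volumes are underestimated by the garment
(positive spirometer-minus-garment bias near 1 L) and the 0.150 L
limits-of-agreement criterion fails for every parameter — a sitting-task
tidal calibration does not extrapolate to vital-capacity excursions.

Individual fits are ordinary R objects with broom-style accessors:

```r
m <- bank_lookup(report$bank, 1, "sitting")
m
#> <rip_calibration> TV_L = 0.602 * TV_raw + -0.0142  (n = 69, R2 = 0.974)
tidy(m)
#> # A tibble: 2 × 3
#>   term        estimate unit
#>   <chr>          <dbl> <chr>
#> 1 intercept_b  -0.0142 L
#> 2 slope_a       0.602  L per a.u.
```

`autoplot(report)` draws per-task box plots of subject biases;
`plot_bland_altman()` draws the classic agreement plot for any paired
series. A thin command-line wrapper is installed as `exec/ripvol`
(`ripvol simulate`, `ripvol run`).

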