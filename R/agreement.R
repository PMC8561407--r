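#' Centered moving average of a tidal-volume series
#'
#' An overlapping centered moving average of `window` breaths, applied
#' identically to both devices' calibrated tidal-volume series before the
#' difference is formed; output length is `length(tv) - window + 1`.
#'
#' @param tv Numeric vector of tidal volumes.
#' @param window Window size in breaths (>= 1); default 5.
#' @return The averaged vector.
#' @export
moving_average_tv <- function(tv, window = 5) {
  if (window < 1) abort("`window` must be >= 1")
  if (window == 1) return(tv)
  if (length(tv) < window) return(numeric(0))
  zoo::rollmean(tv, k = window, align = "center")
}

#' Inter-device tidal-volume difference as a percentage of the reference
#'
#' `100 * (spiro_tv - hex_tv) / spiro_tv`. Under this sign convention an
#' overestimate by the garment yields a negative value.
#'
#' @param spiro_tv Reference (spirometer) tidal volumes in L; must be > 0.
#' @param hex_tv Garment tidal volumes in L (calibrated).
#' @return Percentage differences.
#' @export
diff_tv_percent <- function(spiro_tv, hex_tv) {
  if (length(spiro_tv) != length(hex_tv)) abort("input vectors differ in length")
  if (any(spiro_tv <= 0)) abort("spirometer tidal volumes must be > 0")
  100 * (spiro_tv - hex_tv) / spiro_tv
}

#' Bland-Altman bias and limits of agreement
#'
#' Bias is the mean difference; the limits-of-agreement half-width is
#' 1.96 times the sample SD of the differences (reported as one
#' nonnegative number).
#'
#' @param diffs Numeric vector of differences (any unit), length >= 2.
#' @return A one-row tibble: `bias`, `loa_halfwidth`, `n`.
#' @examples
#' bland_altman(c(-2, 0, 2))
#' @export
bland_altman <- function(diffs) {
  if (length(diffs) < 2) abort("Bland-Altman needs at least 2 differences")
  tibble(bias = mean(diffs), loa_halfwidth = 1.96 * sd(diffs),
         n = length(diffs))
}

#' Per-subject agreement for one task segment
#'
#' Applies the breath-averaging window to both calibrated tidal-volume
#' series, forms the percentage difference and runs a Bland-Altman
#' analysis.
#'
#' @param tvs Tibble with columns `spiro_tv` and `rip_tv` (both in L,
#'   RIP already calibrated), ordered by time.
#' @param window Averaging window in breaths.
#' @return A one-row tibble: `bias` (%), `loa_halfwidth` (%), `n`.
#' @export
subject_agreement <- function(tvs, window = 5) {
  s <- moving_average_tv(tvs$spiro_tv, window)
  h <- moving_average_tv(tvs$rip_tv, window)
  if (length(s) < 2) {
    abort(sprintf("too few breaths (%d) for a %d-breath averaging window",
                  nrow(tvs), window))
  }
  bland_altman(diff_tv_percent(s, h))
}

#' Aggregate per-subject agreement into a task summary
#'
#' The central statistic across subjects is the mean when the per-subject
#' biases pass a Shapiro-Wilk normality test at alpha = 0.05, otherwise the
#' median; the same choice is applied to the bias and the LOA column. Both
#' the mean and the median are always reported alongside the headline
#' value. Criteria flags follow the a priori accuracy bounds.
#'
#' @param per_subject Tibble with one row per subject: columns `bias` and
#'   `loa_halfwidth` (both %).
#' @param bias_limit,loa_limit Accuracy bounds in % (defaults 5 and 15).
#' @return A one-row tibble: `central_bias`, `central_loa`, `n_subjects`,
#'   `meets_bias`, `meets_loa`, `central_stat`, `normality_p`,
#'   `mean_bias`, `median_bias`, `mean_loa`, `median_loa`.
#' @export
summarize_task <- function(per_subject, bias_limit = 5, loa_limit = 15) {
  n <- nrow(per_subject)
  if (n < 2) abort("task summary needs at least 2 subjects")
  p <- if (n >= 3 && sd(per_subject$bias) > 0) {
    shapiro.test(per_subject$bias)$p.value
  } else NA_real_
  normal <- !is.na(p) && p >= 0.05
  central <- if (normal) mean else median
  cb <- central(per_subject$bias)
  cl <- central(per_subject$loa_halfwidth)
  tibble(
    central_bias = cb, central_loa = cl, n_subjects = n,
    meets_bias = abs(cb) < bias_limit, meets_loa = cl < loa_limit,
    central_stat = if (normal) "mean" else "median", normality_p = p,
    mean_bias = mean(per_subject$bias), median_bias = median(per_subject$bias),
    mean_loa = mean(per_subject$loa_halfwidth),
    median_loa = median(per_subject$loa_halfwidth)
  )
}

#' Coefficient of variation
#'
#' Sample SD divided by the mean; used as the repeatability measure across
#' triplicate maneuvers.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return The dimensionless coefficient of variation.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) abort("CoV needs at least 2 values")
  m <- mean(values)
  if (m == 0) abort("CoV undefined for zero mean")
  sd(values) / m
}
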