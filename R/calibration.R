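#' Fit the spirometer-based linear calibration
#'
#' Ordinary least squares of spirometer tidal volume (L) on raw RIP tidal
#' amplitude (a.u.): `TV_L = a * TV_raw + b`. All matched tidal volumes of
#' a task are used. Because the model includes an intercept, the mean
#' signed residual is exactly zero.
#'
#' @param rip_tv Raw RIP tidal amplitudes (a.u.).
#' @param spiro_tv Spirometer tidal volumes (L); same length, >= 3.
#' @param task,subject Optional labels stored with the model.
#' @return An object of class `rip_calibration` with elements `a` (L per
#'   a.u.), `b` (L), `r2`, `n_breaths`, `residuals`, `task`, `subject`,
#'   `session_fit`.
#' @examples
#' m <- fit_calibration(c(1, 2, 3), c(0.5, 1.0, 1.5))
#' c(m$a, m$b)
#' @export
fit_calibration <- function(rip_tv, spiro_tv, task = NA_character_,
                            subject = NA_integer_) {
  if (length(rip_tv) != length(spiro_tv)) abort("input vectors differ in length")
  n <- length(rip_tv)
  if (n < 3) abort("calibration needs at least 3 matched breaths")
  if (var(rip_tv) < .Machine$double.eps) {
    abort("degenerate fit: RIP tidal amplitudes have zero variance")
  }
  fit <- lm(spiro_tv ~ rip_tv)
  a <- unname(coef(fit)[2])
  b <- unname(coef(fit)[1])
  if (a <= 0) {
    warn(sprintf("calibration slope a = %.4g is not positive; fit is physically implausible", a))
  }
  ssr <- sum(fit$residuals^2)
  sst <- sum((spiro_tv - mean(spiro_tv))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  structure(
    list(a = a, b = b, r2 = r2, n_breaths = n,
         residuals = unname(fit$residuals),
         task = task, subject = subject, session_fit = 1L),
    class = "rip_calibration"
  )
}

#' @export
print.rip_calibration <- function(x, ...) {
  cat(sprintf("<rip_calibration> TV_L = %.4g * TV_raw + %.4g  (n = %d, R2 = %.3f)\n",
              x$a, x$b, x$n_breaths, x$r2))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x A `rip_calibration` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rip_calibration <- function(x, ...) {
  tibble(term = c("intercept_b", "slope_a"), estimate = c(x$b, x$a),
         unit = c("L", "L per a.u."))
}

#' @rdname fit_calibration
#' @exportS3Method generics::glance
glance.rip_calibration <- function(x, ...) {
  tibble(r.squared = x$r2, n_breaths = x$n_breaths, subject = x$subject,
         task = x$task, session_fit = x$session_fit)
}

#' Apply a calibration model to raw RIP amplitudes
#'
#' Elementwise `a * x + b`, without clipping. Used both within the fitting
#' session (self-calibration) and for calibration transfer to a later
#' session.
#'
#' @param model A [fit_calibration()] result.
#' @param rip_tv Raw RIP tidal amplitudes (a.u.).
#' @return Calibrated tidal volumes in L.
#' @export
apply_calibration <- function(model, rip_tv) {
  stopifnot(inherits(model, "rip_calibration"))
  model$a * rip_tv + model$b
}

#' Collect session-1 calibration models into a bank
#'
#' One model per included (subject, task); tasks excluded by the
#' unmatchable-data rule are recorded as explicit absences, never filled
#' with a default.
#'
#' @param models List of [fit_calibration()] results (with `subject` and
#'   `task` set).
#' @param missing Optional tibble of absent combinations with columns
#'   `subject`, `task` and `reason`.
#' @return An object of class `rip_calibration_bank`.
#' @export
calibration_bank <- function(models, missing = NULL) {
  tab <- if (length(models)) {
    purrr::map_dfr(models, function(m) {
      tibble(subject = m$subject, task = m$task, a = m$a, b = m$b,
             n_breaths = m$n_breaths, r2 = m$r2)
    })
  } else {
    tibble(subject = integer(0), task = character(0), a = numeric(0),
           b = numeric(0), n_breaths = integer(0), r2 = numeric(0))
  }
  if (is.null(missing)) {
    missing <- tibble(subject = integer(0), task = character(0),
                      reason = character(0))
  }
  keys <- paste(tab$subject, tab$task, sep = "::")
  if (anyDuplicated(keys)) abort("duplicate (subject, task) in calibration bank")
  structure(list(table = tab, models = setNames(models, keys),
                 missing = missing),
            class = "rip_calibration_bank")
}

#' @export
print.rip_calibration_bank <- function(x, ...) {
  cat(sprintf("<rip_calibration_bank> %d models, %d absent\n",
              nrow(x$table), nrow(x$missing)))
  invisible(x)
}

#' Look up a calibration model in a bank
#'
#' A missing combination is an error (with the recorded reason when one
#' exists); there is never a silent fallback.
#'
#' @param bank A [calibration_bank()].
#' @param subject Subject id.
#' @param task Task label.
#' @return The stored `rip_calibration` model.
#' @export
bank_lookup <- function(bank, subject, task) {
  stopifnot(inherits(bank, "rip_calibration_bank"))
  key <- paste(subject, task, sep = "::")
  m <- bank$models[[key]]
  if (is.null(m)) {
    hit <- bank$missing[bank$missing$subject == subject &
                          bank$missing$task == task, ]
    reason <- if (nrow(hit)) paste0(" (", hit$reason[1], ")") else ""
    abort(sprintf("no calibration model for subject %s, task '%s'%s",
                  subject, task, reason))
  }
  m
}
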