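# Candidate local extrema of a sampled signal. Plateaus are handled by
# carrying the last nonzero slope sign; the plateau midpoint is used.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(tibble(index = integer(0), type = character(0)))
  s <- sign(diff(x))
  # carry slope sign through flat runs
  nz <- which(s != 0)
  if (!length(nz)) return(tibble(index = integer(0), type = character(0)))
  filled <- s
  filled[s == 0] <- NA
  filled <- zoo::na.locf(filled, na.rm = FALSE)
  filled <- zoo::na.locf(filled, fromLast = TRUE)
  chg <- which(diff(filled) != 0)           # extremum between chg and chg+1
  if (!length(chg)) return(tibble(index = integer(0), type = character(0)))
  idx <- chg + 1L
  type <- ifelse(filled[chg] > 0, "peak", "trough")
  tibble(index = idx, type = type)
}

# Keep the more extreme of consecutive same-type extrema.
collapse_alternation <- function(ext, x) {
  repeat {
    if (nrow(ext) < 2) return(ext)
    same <- which(ext$type[-1] == ext$type[-nrow(ext)])
    if (!length(same)) return(ext)
    j <- same[1]
    a <- ext$index[j]; b <- ext$index[j + 1]
    drop <- if (ext$type[j] == "peak") {
      if (x[a] >= x[b]) j + 1 else j
    } else {
      if (x[a] <= x[b]) j + 1 else j
    }
    ext <- ext[-drop, ]
  }
}

#' Detect breaths in a volume trace
#'
#' Finds alternating end-expiratory troughs and end-inspiratory peaks.
#' Candidate extrema are pruned iteratively: any trough-peak excursion
#' smaller than `min_prominence_frac` times the running-median tidal
#' excursion, or with its two extrema closer than `min_breath_s / 2`, is
#' treated as noise and removed (weakest first), merging its neighbours.
#' Each remaining trough followed by a peak is one breath; tidal volume is
#' the level difference.
#'
#' @param volume A [signal_trace()] of (relative) volume.
#' @param min_breath_s Minimum plausible breath duration in seconds.
#' @param min_prominence_frac Excursion threshold as a fraction of the
#'   running-median excursion.
#' @return A tibble of breath records: `breath_index`, `t_end_exp`,
#'   `t_end_insp` (s), `level_end_exp`, `level_end_insp`, `tv` (trace
#'   units). Zero rows when no breaths are detectable.
#' @export
detect_breaths <- function(volume, min_breath_s = 1, min_prominence_frac = 0.2) {
  stopifnot(is_trace(volume))
  if (trace_duration(volume) < 2 * min_breath_s) {
    abort("trace must span at least two minimum breath durations")
  }
  x <- volume$samples
  tt <- trace_times(volume)
  ext <- local_extrema(x)
  if (!nrow(ext)) return(empty_breaths())
  ext <- collapse_alternation(ext, x)
  # boundary end-expirations: the segment starts/ends at an expiratory level
  if (ext$type[1] == "peak" && ext$index[1] > 1) {
    i0 <- which.min(x[1:ext$index[1]])
    if (i0 < ext$index[1]) {
      ext <- dplyr::bind_rows(tibble(index = i0, type = "trough"), ext)
    }
  }
  last <- nrow(ext)
  if (ext$type[last] == "peak" && ext$index[last] < length(x)) {
    tail_idx <- ext$index[last]:length(x)
    i1 <- tail_idx[which.min(x[tail_idx])]
    if (i1 > ext$index[last]) {
      ext <- dplyr::bind_rows(ext, tibble(index = i1, type = "trough"))
    }
  }
  # iterative pruning of sub-threshold or too-fast excursions
  repeat {
    if (nrow(ext) < 2) break
    amp <- abs(diff(x[ext$index]))
    dt <- diff(tt[ext$index])
    k <- min(11L, (length(amp) %/% 2L) * 2L + 1L)
    ref <- if (length(amp) >= 3) stats::runmed(amp, k) else rep(median(amp), length(amp))
    bad <- amp < min_prominence_frac * ref | dt < min_breath_s / 2
    if (!any(bad)) break
    j <- which(bad)[which.min(amp[bad])]
    ext <- ext[-c(j, j + 1), ]
    ext <- collapse_alternation(ext, x)
  }
  if (nrow(ext) < 2) return(empty_breaths())
  troughs <- which(ext$type == "trough")
  troughs <- troughs[troughs < nrow(ext)]
  pairs <- troughs[ext$type[troughs + 1] == "peak"]
  if (!length(pairs)) return(empty_breaths())
  it <- ext$index[pairs]
  ip <- ext$index[pairs + 1]
  tibble(
    breath_index = seq_along(pairs),
    t_end_exp = tt[it], t_end_insp = tt[ip],
    level_end_exp = x[it], level_end_insp = x[ip],
    tv = x[ip] - x[it]
  )
}

empty_breaths <- function() {
  tibble(breath_index = integer(0), t_end_exp = numeric(0),
         t_end_insp = numeric(0), level_end_exp = numeric(0),
         level_end_insp = numeric(0), tv = numeric(0))
}

#' Match breaths between spirometer and RIP
#'
#' Greedy one-to-one nearest-in-time pairing on end-inspiration times
#' (smallest `|dt|` first; ties broken toward the earlier RIP breath),
#' keeping only pairs with `|dt| <= tol_s`. The unmatched fraction is
#' `1 - 2 * n_pairs / (n_spiro + n_rip)`; a segment with more than 50 %
#' unmatchable data is flagged for exclusion from further analysis.
#'
#' @param spiro,rip Breath tibbles from [detect_breaths()], on a common
#'   (already lag-corrected) clock.
#' @param tol_s Matching tolerance in seconds.
#' @return A list of class `rip_match`: `pairs` tibble (`t_s`,
#'   `spiro_index`, `rip_index`, `dt_s`, `spiro_tv`, `rip_tv`),
#'   `n_spiro`, `n_rip`, `unmatched_fraction`, `excluded`.
#' @export
match_breaths <- function(spiro, rip, tol_s = 0.5) {
  ns <- nrow(spiro)
  nr <- nrow(rip)
  empty_pairs <- tibble(t_s = numeric(0), spiro_index = integer(0),
                        rip_index = integer(0), dt_s = numeric(0),
                        spiro_tv = numeric(0), rip_tv = numeric(0))
  if (ns == 0 && nr == 0) {
    return(structure(list(pairs = empty_pairs, n_spiro = 0L, n_rip = 0L,
                          unmatched_fraction = 1, excluded = TRUE),
                     class = "rip_match"))
  }
  cand <- tidyr::expand_grid(spiro_index = seq_len(ns), rip_index = seq_len(nr))
  if (nrow(cand)) {
    cand$dt_s <- rip$t_end_insp[cand$rip_index] - spiro$t_end_insp[cand$spiro_index]
    cand <- cand[abs(cand$dt_s) <= tol_s, ]
    cand <- cand[order(abs(cand$dt_s), rip$t_end_insp[cand$rip_index]), ]
  }
  used_s <- logical(ns)
  used_r <- logical(nr)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    si <- cand$spiro_index[i]; ri <- cand$rip_index[i]
    if (!used_s[si] && !used_r[ri]) {
      keep[i] <- TRUE
      used_s[si] <- TRUE
      used_r[ri] <- TRUE
    }
  }
  cand <- cand[keep, ]
  pairs <- if (nrow(cand)) {
    tibble(t_s = spiro$t_end_insp[cand$spiro_index],
           spiro_index = cand$spiro_index, rip_index = cand$rip_index,
           dt_s = cand$dt_s,
           spiro_tv = spiro$tv[cand$spiro_index],
           rip_tv = rip$tv[cand$rip_index]) |>
      dplyr::arrange(.data$t_s)
  } else empty_pairs
  uf <- 1 - 2 * nrow(pairs) / (ns + nr)
  structure(list(pairs = pairs, n_spiro = ns, n_rip = nr,
                 unmatched_fraction = uf, excluded = uf > 0.5),
            class = "rip_match")
}

#' @export
print.rip_match <- function(x, ...) {
  cat(sprintf("<rip_match> %d pairs (spiro %d, rip %d), unmatched %.0f%%%s\n",
              nrow(x$pairs), x$n_spiro, x$n_rip, 100 * x$unmatched_fraction,
              if (x$excluded) " -> EXCLUDED" else ""))
  invisible(x)
}

#' Paired tidal-volume series from a match result
#'
#' @param match A [match_breaths()] result that is not excluded.
#' @return A tibble ordered by time with columns `t_s`, `spiro_tv` (L) and
#'   `rip_tv` (a.u. or L, depending on calibration state).
#' @export
tv_series <- function(match) {
  stopifnot(inherits(match, "rip_match"))
  if (match$excluded) {
    abort(sprintf("task excluded (unmatched %.0f%%)",
                  100 * match$unmatched_fraction))
  }
  match$pairs[, c("t_s", "spiro_tv", "rip_tv")]
}
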