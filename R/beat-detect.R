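## Pan-Tompkins style QRS detection: zero-phase 5-15 Hz band-pass,
## five-point derivative, squaring, 150 ms moving-window integration,
## dual adaptive thresholds with search-back, 200 ms refractory, and
## final R-peak re-localization on the band-passed signal.

#' Beat series container
#'
#' Strictly increasing R-peak times with their sample indices.
#'
#' @param times Numeric vector of peak times in seconds, strictly increasing.
#' @param indices Integer vector of 1-based peak sample indices.
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `beat_series`.
#' @export
beat_series <- function(times, indices, sampling_rate) {
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stopf("peak times must be strictly increasing")
  }
  structure(list(times = as.numeric(times), indices = as.integer(indices),
                 sampling_rate = sampling_rate),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats", length(x$times)))
  if (length(x$times) > 1L) {
    cat(sprintf(", mean IBI %.3f s", mean(diff(x$times))))
  }
  cat("\n")
  invisible(x)
}

#' Detect R peaks with a Pan-Tompkins style detector
#'
#' The classic pipeline: zero-phase 5--15 Hz Butterworth band-pass, a
#' five-point derivative, squaring, 150 ms moving-window integration, then
#' dual adaptive thresholds over integration-peak candidates with a 200 ms
#' refractory period and a search-back pass for missed beats. Each accepted
#' peak is finally re-localized at the band-passed signal's local maximum
#' within +-75 ms, which removes the integrator's group delay.
#'
#' @param record An [ecg_record()] at least 2 s long.
#' @return A [beat_series()]; an empty series for a flat or beat-free signal.
#' @export
detect_beats <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$sampling_rate
  x <- record$samples
  if (length(x) < 2 * fs) stopf("record must be at least 2 s long")
  empty <- beat_series(numeric(0), integer(0), fs)
  if (all(x == x[1])) return(empty)

  bt <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  bp <- filtfilt_refl(bt$b, bt$a, x)

  # five-point derivative (1/8)(2x[n] + x[n-1] - x[n-3] - 2x[n-4])
  dv <- as.numeric(stats::filter(bp, c(2, 1, 0, -1, -2) / 8, sides = 2))
  dv[is.na(dv)] <- 0
  sq <- dv^2
  w <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  refr <- round(0.200 * fs)
  cand <- local_maxima(mwi, min_dist = refr)
  cand <- cand[mwi[cand] > 0]
  if (length(cand) == 0L) return(empty)

  # adaptive signal / noise levels initialized from the first 2 s
  init <- mwi[1:min(length(mwi), round(2 * fs))]
  spki <- max(init) * 0.5
  npki <- mean(init) * 0.5
  thr <- function() npki + 0.25 * (spki - npki)

  peaks <- integer(0)
  rr_hist <- numeric(0)
  last_qrs <- -Inf
  rejected <- integer(0)
  for (i in cand) {
    pk <- mwi[i]
    if (i - last_qrs < refr) next
    if (pk > thr()) {
      peaks <- c(peaks, i)
      spki <- 0.125 * pk + 0.875 * spki
      if (length(peaks) > 1L) {
        rr_hist <- c(rr_hist, i - peaks[length(peaks) - 1L])
        if (length(rr_hist) > 8L) rr_hist <- tail(rr_hist, 8L)
      }
      last_qrs <- i
    } else {
      npki <- 0.125 * pk + 0.875 * npki
      rejected <- c(rejected, i)
      # search-back: a long gap since the last QRS re-examines the best
      # rejected candidate in the gap at half threshold
      if (length(rr_hist) >= 2L && is.finite(last_qrs) &&
          (i - last_qrs) > 1.66 * mean(rr_hist)) {
        gap <- rejected[rejected > last_qrs + refr & rejected < i]
        if (length(gap)) {
          j <- gap[which.max(mwi[gap])]
          if (mwi[j] > 0.5 * thr()) {
            peaks <- c(peaks, j)
            spki <- 0.25 * mwi[j] + 0.75 * spki
            rr_hist <- c(rr_hist, j - last_qrs)
            if (length(rr_hist) > 8L) rr_hist <- tail(rr_hist, 8L)
            last_qrs <- j
          }
        }
      }
    }
  }
  if (length(peaks) == 0L) return(empty)
  peaks <- sort(peaks)

  # re-localize each detection at the band-passed local maximum (+-75 ms)
  hw <- round(0.075 * fs)
  n <- length(bp)
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, as.integer(i - hw)); hi <- min(n, as.integer(i + hw))
    lo + which.max(bp[lo:hi]) - 1L
  }, integer(1))
  refined <- unique(refined)
  if (length(refined) > 1L) {
    keep <- c(TRUE, diff(refined) >= refr)
    refined <- refined[keep]
  }
  beat_series((refined - 1) / fs, refined, fs)
}

# indices of strict local maxima separated by at least `min_dist` samples
# (greedy, highest first)
local_maxima <- function(x, min_dist = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  is_max <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  if (length(is_max) <= 1L || min_dist <= 1L) return(is_max)
  ord <- is_max[order(x[is_max], decreasing = TRUE)]
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(taken - i) >= min_dist)) taken <- c(taken, i)
  }
  sort(taken)
}

#' Interbeat-interval series
#'
#' Ordered IBIs in seconds, each with the onset time of its opening beat
#' and a stress label. Optional `segment_start`/`segment_end` attributes
#' carry the containing segment's bounds for window segmentation.
#'
#' @param onset Numeric vector of onset times (seconds).
#' @param ibi Numeric vector of intervals (seconds, > 0).
#' @param label Stress label (single value or per-interval vector).
#' @param segment_start,segment_end Optional segment bounds in seconds.
#' @return A tibble of class `ibi_series` with columns `onset`, `ibi`,
#'   `label`.
#' @export
ibi_series <- function(onset, ibi, label = NA,
                       segment_start = NULL, segment_end = NULL) {
  if (length(onset) != length(ibi)) stopf("`onset` and `ibi` lengths differ")
  if (any(ibi <= 0)) stopf("all intervals must be > 0")
  lab <- if (all(is.na(label))) {
    factor(rep(NA_character_, length(ibi)), levels = stress_levels())
  } else {
    rep(as_stress_factor(label), length.out = length(ibi))
  }
  out <- tibble::tibble(onset = as.numeric(onset), ibi = as.numeric(ibi),
                        label = lab)
  attr(out, "segment_start") <- segment_start
  attr(out, "segment_end") <- segment_end
  class(out) <- c("ibi_series", class(out))
  out
}

#' Convert detected beats to an interbeat-interval series
#'
#' Intervals are successive differences of the peak times; each interval's
#' onset is the time of its opening beat. Fewer than two beats yield an
#' empty series.
#'
#' @param beats A [beat_series()].
#' @param label Stress label for the segment (optional).
#' @return An [ibi_series()].
#' @export
beats_to_ibis <- function(beats, label = NA) {
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats$times) < 2L) {
    return(ibi_series(numeric(0), numeric(0), label))
  }
  ibi_series(onset = beats$times[-length(beats$times)],
             ibi = diff(beats$times), label = label)
}

#' Keep only physiologically plausible intervals
#'
#' Removes intervals outside the closed range `[low, high]` (defaults
#' 0.6--1.2 s), preserving order. Both endpoints are retained: the picture
#' bin scheme's final cell is closed at 1.2 s, so 1.2 s is encodable, and
#' the bound is applied symmetrically at 0.6 s.
#'
#' @param ibis An [ibi_series()].
#' @param low,high Closed plausibility bounds in seconds.
#' @return The filtered [ibi_series()].
#' @export
filter_plausible <- function(ibis, low = 0.6, high = 1.2) {
  stopifnot(inherits(ibis, "ibi_series"))
  if (low >= high) stopf("`low` must be below `high`")
  keep <- ibis$ibi >= low & ibis$ibi <= high
  out <- ibis[keep, ]
  attr(out, "segment_start") <- attr(ibis, "segment_start")
  attr(out, "segment_end") <- attr(ibis, "segment_end")
  class(out) <- class(ibis)
  out
}

#' Middle window of a phase
#'
#' Returns the centred window of length `keep` inside `[start, end]`, the
#' rule used to discard state-transition effects at phase boundaries
#' (e.g. the middle 300 s of a 330 s phase is `[15, 315]` relative to its
#' start).
#'
#' @param start,end Phase bounds in seconds.
#' @param keep Window length in seconds; must not exceed the phase duration.
#' @return Numeric length-2 vector `c(lo, hi)` in absolute seconds.
#' @export
middle_window <- function(start, end, keep) {
  dur <- end - start
  if (keep > dur + 1e-9) stopf("`keep` (%g s) exceeds phase duration (%g s)", keep, dur)
  pad <- (dur - keep) / 2
  c(start + pad, end - pad)
}

#' Trim a phase to its centred middle window
#'
#' For an [ibi_series()], keeps intervals whose onset lies in the middle
#' `keep` seconds of the phase; for an [ecg_record()] (single phase), crops
#' the samples to that window. `keep` equal to the phase length is the
#' identity.
#'
#' @param x An [ibi_series()] or [ecg_record()].
#' @param keep Window length in seconds.
#' @param start,end Phase bounds in seconds; for an `ibi_series` they
#'   default to its `segment_start`/`segment_end` attributes, for an
#'   `ecg_record` to the full record.
#' @param mode Only `"middle"` is supported.
#' @return Same type as `x`, trimmed.
#' @export
trim_phase <- function(x, keep, start = NULL, end = NULL, mode = "middle") {
  stopifnot(identical(mode, "middle"))
  UseMethod("trim_phase")
}

#' @export
trim_phase.ibi_series <- function(x, keep, start = NULL, end = NULL,
                                  mode = "middle") {
  start <- start %||% attr(x, "segment_start") %||% min(x$onset, 0)
  end <- end %||% attr(x, "segment_end") %||% max(x$onset + x$ibi)
  win <- middle_window(start, end, keep)
  out <- x[x$onset >= win[1] & x$onset < win[2], ]
  attr(out, "segment_start") <- win[1]
  attr(out, "segment_end") <- win[2]
  class(out) <- class(x)
  out
}

#' @export
trim_phase.ecg_record <- function(x, keep, start = NULL, end = NULL,
                                  mode = "middle") {
  fs <- x$sampling_rate
  start <- start %||% 0
  end <- end %||% record_duration(x)
  win <- middle_window(start, end, keep)
  i0 <- floor(win[1] * fs) + 1L
  i1 <- min(length(x$samples), ceiling(win[2] * fs))
  ecg_record(x$samples[i0:i1], fs)
}
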