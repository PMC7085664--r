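#' Slide feature windows over a segment's IBI series
#'
#' Advances a window of `window` seconds by `window - overlap` seconds
#' across the segment (default 10 s windows with 8 s overlap). An interval
#' belongs to a window iff its onset time lies in `[start, end)`; the
#' trailing partial window is dropped, so a segment of length T yields
#' `floor((T - window)/(window - overlap)) + 1` windows. Windows never
#' cross segment boundaries because they are built per segment.
#'
#' @param ibis A single-segment [ibi_series()] carrying
#'   `segment_start`/`segment_end` attributes (or pass bounds explicitly).
#' @param window Window length in seconds.
#' @param overlap Overlap between consecutive windows in seconds
#'   (`0 <= overlap < window`).
#' @param segment_start,segment_end Segment bounds in seconds.
#' @return A tibble of class `feature_windows` with columns `start`, `end`,
#'   `label` and a list-column `intervals`.
#' @export
segment_windows <- function(ibis, window = 10, overlap = 8,
                            segment_start = NULL, segment_end = NULL) {
  stopifnot(inherits(ibis, "ibi_series"))
  if (!(window > overlap && overlap >= 0)) {
    stopf("need window > overlap >= 0")
  }
  s0 <- segment_start %||% attr(ibis, "segment_start") %||%
    (if (nrow(ibis)) min(ibis$onset) else 0)
  s1 <- segment_end %||% attr(ibis, "segment_end") %||%
    (if (nrow(ibis)) max(ibis$onset + ibis$ibi) else 0)
  step <- window - overlap
  if (s1 - s0 < window) {
    warning("segment shorter than one window; no feature windows produced")
    starts <- numeric(0)
  } else {
    n_win <- floor((s1 - s0 - window) / step) + 1
    starts <- s0 + (seq_len(n_win) - 1) * step
  }
  lab <- if (nrow(ibis)) ibis$label[1] else factor(NA, levels = stress_levels())
  out <- tibble::tibble(
    start = starts,
    end = starts + window,
    label = rep(lab, length(starts)),
    intervals = lapply(starts, function(st) {
      ibis$ibi[ibis$onset >= st & ibis$onset < st + window]
    })
  )
  class(out) <- c("feature_windows", class(out))
  out
}

#' Time-domain HRV features
#'
#' The three classical time-domain heart-rate-variability summaries of an
#' interval sequence: `mean_ibi` is the arithmetic mean; `sdnn` the sample
#' standard deviation (n-1 denominator); `rmssd` the root mean square of
#' successive differences (n-1 difference terms, n-1 denominator).
#'
#' @param intervals Numeric vector of interbeat intervals in seconds
#'   (`mean_ibi` needs n >= 1, the other two n >= 2).
#' @return Seconds (scalar).
#' @export
#' @examples
#' mean_ibi(c(0.7, 0.9))  # 0.8
#' sdnn(c(0.7, 0.9))      # 0.1414...
#' rmssd(c(0.7, 0.9))     # 0.2
mean_ibi <- function(intervals) {
  if (length(intervals) < 1L) stopf("`mean_ibi` needs at least one interval")
  mean(intervals)
}

#' @rdname mean_ibi
#' @export
sdnn <- function(intervals) {
  if (length(intervals) < 2L) stopf("`sdnn` needs at least two intervals")
  sd(intervals)
}

#' @rdname mean_ibi
#' @export
rmssd <- function(intervals) {
  if (length(intervals) < 2L) stopf("`rmssd` needs at least two intervals")
  d <- diff(intervals)
  sqrt(sum(d^2) / length(d))
}

#' Assemble the HRV feature table
#'
#' One row per feature window with at least two intervals (windows with
#' fewer are skipped with a message), columns in the canonical order
#' `mean_ibi`, `sdnn`, `rmssd`, plus the window start and label.
#'
#' @param windows A [segment_windows()] result, or a list of them (one per
#'   segment) which is row-bound.
#' @return A tibble with columns `window_start`, `mean_ibi`, `sdnn`,
#'   `rmssd`, `label`.
#' @export
feature_table <- function(windows) {
  if (!inherits(windows, "feature_windows") && is.list(windows)) {
    windows <- do.call(rbind, windows)
  }
  keep <- vapply(windows$intervals, length, integer(1)) >= 2L
  if (any(!keep)) {
    message(sum(!keep), " window(s) with < 2 intervals skipped")
  }
  w <- windows[keep, ]
  tibble::tibble(
    window_start = w$start,
    mean_ibi = vapply(w$intervals, mean_ibi, numeric(1)),
    sdnn = vapply(w$intervals, sdnn, numeric(1)),
    rmssd = vapply(w$intervals, rmssd, numeric(1)),
    label = w$label
  )
}
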