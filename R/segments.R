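#' Cut a session's IBI series into labelled analysis segments
#'
#' Applies the protocol's segment rule to a whole-session IBI series: the
#' middle `keep_long` seconds of the rest phase give the LP segment, the
#' middle `keep_long` seconds of the first normal-driving phase the NP
#' segment, and the middle `keep_short` seconds of each calculation phase
#' the HP segments. Later normal-driving phases are not used by default
#' (set `use_all_phases = TRUE` to keep every phase, trimmed by label).
#' An IBI belongs to a segment if its onset lies inside the segment window.
#'
#' @param ibis An [ibi_series()] covering the session (onsets in session
#'   time); labels are overwritten by the timeline's.
#' @param timeline The [session_timeline()] the session was recorded under.
#' @param keep_long Middle-window length for 330 s phases (default 300).
#' @param keep_short Middle-window length for 180 s phases (default 150).
#' @param use_all_phases Keep every phase rather than the protocol's four
#'   analysis segments.
#' @return A list of [ibi_series()], one per segment in chronological
#'   order, each carrying its segment bounds and single label.
#' @export
session_segments <- function(ibis, timeline = default_timeline(),
                             keep_long = 300, keep_short = 150,
                             use_all_phases = FALSE) {
  stopifnot(inherits(ibis, "ibi_series"), inherits(timeline, "session_timeline"))
  use <- if (use_all_phases) {
    seq_len(nrow(timeline))
  } else {
    first_lp <- which(timeline$label == "LP")[1]
    first_np <- which(timeline$label == "NP")[1]
    hps <- which(timeline$label == "HP")
    sort(c(first_lp, first_np, hps))
  }
  segs <- lapply(use, function(k) {
    ph <- timeline[k, ]
    keep <- if (ph$duration >= keep_long) keep_long else
      min(keep_short, ph$duration)
    win <- middle_window(ph$start, ph$end, keep)
    sel <- ibis$onset >= win[1] & ibis$onset < win[2]
    ibi_series(ibis$onset[sel], ibis$ibi[sel], label = ph$label,
               segment_start = win[1], segment_end = win[2])
  })
  names(segs) <- timeline$name[use]
  segs
}

#' Ground-truth analysis segments straight from the generator
#'
#' Convenience wrapper: runs [session_segments()] on a synthesized
#' session's true IBI series, bypassing waveform rendering and detection.
#' Used for classifier experiments where detector error is not under study.
#'
#' @param timeline,model,seed Passed to the IBI sampler as in
#'   [synthesize_ecg()].
#' @param ... Passed on to [session_segments()].
#' @return A list of [ibi_series()].
#' @export
synthetic_segments <- function(timeline = default_timeline(),
                               model = ibi_state_model(), seed = 1L, ...) {
  beats <- generate_beats(timeline, model, seed)
  tb <- beats$time
  all <- ibi_series(tb[-length(tb)], diff(tb),
                    label = beats$label[-length(tb)])
  session_segments(all, timeline, ...)
}
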