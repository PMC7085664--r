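#' Session timelines
#'
#' A session timeline is an ordered set of contiguous experimental phases,
#' each with a name, a duration in seconds and a stress label. Phases start
#' at time 0 and abut one another.
#'
#' @param name Character vector of phase names.
#' @param duration Numeric vector of phase durations in seconds (all > 0).
#' @param label Stress label per phase (`"LP"`, `"NP"` or `"HP"`).
#'
#' @return A tibble of class `session_timeline` with columns `name`,
#'   `duration`, `label`, `start`, `end` (seconds).
#' @export
#' @examples
#' session_timeline("rest", 60, "LP")
session_timeline <- function(name, duration, label) {
  if (length(name) == 0L) stopf("a timeline needs at least one phase")
  if (any(!is.finite(duration)) || any(duration <= 0)) {
    stopf("phase durations must be positive and finite")
  }
  label <- as_stress_factor(label)
  end <- cumsum(duration)
  out <- tibble::tibble(
    name = as.character(name),
    duration = as.numeric(duration),
    label = label,
    start = end - duration,
    end = end
  )
  class(out) <- c("session_timeline", class(out))
  out
}

#' Default driving-simulator session timeline
#'
#' The six recorded phases of the driving-simulator protocol (the practice
#' phase is not recorded): rest (5 min 30 s, LP), normal driving 1
#' (5 min 30 s, NP), calculations 1 (3 min, HP), normal driving 2
#' (5 min 30 s, NP), calculations 2 (3 min, HP), normal driving 3
#' (5 min 30 s, NP). Total 1680 s.
#'
#' @return A [session_timeline()] with six phases.
#' @export
#' @examples
#' tl <- default_timeline()
#' sum(tl$duration)  # 1680
default_timeline <- function() {
  session_timeline(
    name = c("rest", "normal_driving_1", "calculations_1",
             "normal_driving_2", "calculations_2", "normal_driving_3"),
    duration = c(330, 330, 180, 330, 180, 330),
    label = c("LP", "NP", "HP", "NP", "HP", "NP")
  )
}
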