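#' PQRST beat template
#'
#' One heartbeat as a sum of five smooth Gaussian bumps (P, Q, R, S, T)
#' positioned relative to the R apex, with the R amplitude normalized to 1.
#' Returned as a function of time-from-R-peak in seconds, supported on
#' `[-0.35, 0.45]` s.
#'
#' @return A function `f(t)` mapping seconds (relative to the R peak) to
#'   normalized voltage.
#' @export
#' @examples
#' tpl <- pqrst_template()
#' tpl(0)   # R apex, 1 by construction
pqrst_template <- function() {
  # centre (s), amplitude, width (s) of each wave
  waves <- list(
    P = c(-0.200,  0.12, 0.025),
    Q = c(-0.035, -0.14, 0.010),
    R = c( 0.000,  1.00, 0.011),
    S = c( 0.035, -0.22, 0.010),
    T = c( 0.250,  0.30, 0.045)
  )
  raw <- function(t) {
    y <- 0
    for (w in waves) y <- y + w[2] * exp(-((t - w[1])^2) / (2 * w[3]^2))
    y
  }
  peak <- raw(0)
  function(t) {
    y <- raw(t) / peak
    y[t < -0.35 | t > 0.45] <- 0
    y
  }
}

template_support <- c(-0.35, 0.45)

# Continuous ground-truth beat train across the whole session: the heart
# does not restart at phase boundaries, so beats are chained, each phase
# drawing its IBIs from that phase's state distribution. The first beat is
# placed just inside the record (on the sample grid) so its template
# renders fully.
generate_beats <- function(timeline, model, seed, fs = NULL) {
  t0 <- 0.36
  if (!is.null(fs)) t0 <- round(t0 * fs) / fs
  t_cur <- t0
  beats <- vector("list", nrow(timeline))
  for (k in seq_len(nrow(timeline))) {
    ph <- timeline[k, ]
    span <- ph$end - t_cur
    times <- numeric(0)
    if (span > 0) {
      iv <- sample_ibis(model, ph$label, span + 2 * max(model$means),
                        seed = as.integer(seed) + 1000L * k)
      tt <- t_cur + cumsum(iv)
      if (k == 1L) tt <- c(t_cur, tt)
      times <- tt[tt < ph$end]
    }
    if (length(times)) t_cur <- times[length(times)]
    beats[[k]] <- tibble::tibble(time = times, phase = k, label = ph$label)
  }
  out <- do.call(rbind, beats)
  # the session ends after the last complete beat: a beat whose template
  # would be cut off by the record edge is neither rendered nor ground truth
  out[out$time <= max(timeline$end) - template_support[2], ]
}

#' Synthesize a protocol-structured ECG session
#'
#' Generates ground-truth beat times phase by phase from the state IBI
#' model, then renders a clean ECG by placing one PQRST template at each
#' beat. The record is annotated with the timeline's phases, and the exact
#' beat times, per-phase IBIs and per-beat labels are returned alongside.
#'
#' @param timeline A [session_timeline()]; defaults to [default_timeline()].
#' @param model An [ibi_state_model()].
#' @param sampling_rate Sampling rate in Hz; at least 100 Hz is required to
#'   resolve the beat template. Default 500 Hz.
#' @param seed Integer seed controlling the IBI draws.
#'
#' @return A list with elements `record` (an [ecg_record()]) and `truth`, a
#'   list with `beats` (tibble: `time`, `phase`, `label`), and `ibis`
#'   (tibble: `onset`, `ibi`, `phase`, `label` — successive within-phase
#'   beat differences).
#' @export
synthesize_ecg <- function(timeline = default_timeline(),
                           model = ibi_state_model(),
                           sampling_rate = 500,
                           seed = 1L) {
  stopifnot(inherits(timeline, "session_timeline"))
  if (sampling_rate < 100) {
    stopf("`sampling_rate` below 100 Hz cannot resolve the beat template")
  }
  fs <- sampling_rate
  total <- sum(timeline$duration)
  n <- round(total * fs)

  beats <- generate_beats(timeline, model, seed, fs = fs)

  samples <- numeric(n)
  half <- template_support
  tpl <- pqrst_template()
  for (tb in beats$time) {
    i0 <- max(1L, floor((tb + half[1]) * fs) + 1L)
    i1 <- min(n, ceiling((tb + half[2]) * fs) + 1L)
    if (i1 < i0) next
    idx <- i0:i1
    samples[idx] <- samples[idx] + tpl((idx - 1) / fs - tb)
  }

  ann <- tibble::tibble(
    name = timeline$name,
    start_sample = round(timeline$start * fs) + 1L,
    end_sample = pmin(n, round(timeline$end * fs)),
    label = timeline$label
  )
  record <- ecg_record(samples, fs, ann)

  ibis <- do.call(rbind, lapply(split(beats, beats$phase), function(b) {
    if (nrow(b) < 2L) return(NULL)
    tibble::tibble(onset = b$time[-nrow(b)], ibi = diff(b$time),
                   phase = b$phase[1], label = b$label[1])
  }))
  rownames(ibis) <- NULL
  list(record = record, truth = list(beats = beats, ibis = ibis))
}

#' Noise specification for synthetic ECG
#'
#' Amplitudes are expressed as fractions of the (unit) R-peak amplitude.
#' Defaults emulate the two noise sources removed by preprocessing —
#' 50 Hz powerline interference and slow baseline wander — plus a small
#' broadband measurement noise floor.
#'
#' @param powerline_hz Mains frequency in Hz (50 by default; 60 for
#'   60 Hz regions).
#' @param powerline_amp Powerline sinusoid amplitude.
#' @param wander_band Length-2 Hz band of the baseline wander sinusoids.
#' @param wander_amp Peak amplitude of the summed baseline wander.
#' @param white_sd Standard deviation of additive white noise.
#'
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(powerline_hz = 50, powerline_amp = 0.25,
                       wander_band = c(0.05, 0.5), wander_amp = 0.4,
                       white_sd = 0.02) {
  if (any(c(powerline_amp, wander_amp, white_sd) < 0)) {
    stopf("noise amplitudes must be >= 0")
  }
  if (powerline_hz <= 0) stopf("`powerline_hz` must be > 0")
  if (wander_band[1] <= 0 || wander_band[1] >= wander_band[2]) {
    stopf("invalid `wander_band`")
  }
  structure(list(powerline_hz = powerline_hz, powerline_amp = powerline_amp,
                 wander_band = wander_band, wander_amp = wander_amp,
                 white_sd = white_sd),
            class = "noise_spec")
}

#' Add powerline, baseline-wander and white noise to an ECG record
#'
#' Output is `input + powerline sinusoid + band-limited wander + white
#' noise`, same length and sampling rate. With all amplitudes zero the
#' record is returned unchanged.
#'
#' @param record An [ecg_record()].
#' @param spec A [noise_spec()].
#' @param seed Integer seed; a fixed seed reproduces the noise realization.
#'
#' @return The noisy [ecg_record()].
#' @export
add_noise <- function(record, spec = noise_spec(), seed = 1L) {
  stopifnot(inherits(record, "ecg_record"), inherits(spec, "noise_spec"))
  fs <- record$sampling_rate
  if (spec$powerline_amp > 0 && spec$powerline_hz >= fs / 2) {
    stopf("powerline frequency must be below the Nyquist frequency")
  }
  t <- record_times(record)
  x <- record$samples

  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  on.exit(.restore_seed(old), add = TRUE)

  if (spec$powerline_amp > 0) {
    x <- x + spec$powerline_amp *
      sin(2 * pi * spec$powerline_hz * t + runif(1, 0, 2 * pi))
  }
  if (spec$wander_amp > 0) {
    k <- 8L
    freqs <- runif(k, spec$wander_band[1], spec$wander_band[2])
    phases <- runif(k, 0, 2 * pi)
    amps <- runif(k, 0.3, 1)
    w <- numeric(length(t))
    for (j in seq_len(k)) {
      w <- w + amps[j] * sin(2 * pi * freqs[j] * t + phases[j])
    }
    w <- w / max(abs(w)) * spec$wander_amp
    x <- x + w
  }
  if (spec$white_sd > 0) x <- x + rnorm(length(x), 0, spec$white_sd)

  with_samples(record, x)
}
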