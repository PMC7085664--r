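# Shared fixtures, memoised so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# 60 s single-phase session with constant 0.8 s IBIs, clean
fix_const_session <- function() fixture("const", {
  synthesize_ecg(session_timeline("a", 60, "NP"),
                 ibi_state_model(sds = c(LP = 0, NP = 0, HP = 0)),
                 sampling_rate = 500, seed = 1)
})

# 60 s single-phase session with the default variable model, clean
fix_var_session <- function() fixture("var", {
  synthesize_ecg(session_timeline("a", 60, "NP"), ibi_state_model(),
                 sampling_rate = 500, seed = 2)
})

# full default-protocol session, clean, ground truth attached
fix_full_session <- function() fixture("full", {
  synthesize_ecg(seed = 21)
})

# ground-truth analysis segments of a default session (no waveform step)
fix_segments <- function() fixture("segments", {
  synthetic_segments(seed = 11)
})

# fraction of reference beats recovered within `tol` seconds
beat_sensitivity <- function(detected, truth_times, tol) {
  if (!length(truth_times)) return(NA_real_)
  mean(vapply(truth_times,
              function(t) any(abs(detected - t) <= tol), logical(1)))
}

# fraction of detections matching a reference beat within `tol` seconds
beat_ppv <- function(detected, truth_times, tol) {
  if (!length(detected)) return(NA_real_)
  mean(vapply(detected,
              function(t) any(abs(truth_times - t) <= tol), logical(1)))
}

# independent two-pass oracles for the HRV formulas and RSD
oracle_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}
oracle_sdnn <- function(x) {
  m <- oracle_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / (length(x) - 1))
}
oracle_rmssd <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + (x[i + 1] - x[i])^2
  sqrt(s / (length(x) - 1))
}
oracle_rsd <- function(x) oracle_sdnn(x) / oracle_mean(x)

rms <- function(x) sqrt(mean(x^2))
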