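#' State-dependent interbeat-interval model
#'
#' Generative model for interbeat intervals (IBIs) under each stress level:
#' a truncated Gaussian with optional lag-1 (AR(1)) correlation. Defaults
#' place the three states at distinct means inside the 0.6--1.2 s
#' plausibility band: LP 0.90 s, NP 0.80 s, HP 0.70 s, common sd 0.04 s.
#'
#' @param means Named numeric vector of per-state mean IBIs in seconds;
#'   names must be the three stress levels.
#' @param sds Named numeric vector of per-state IBI standard deviations in
#'   seconds (recycled if length one).
#' @param rho Lag-1 beat-to-beat correlation, in `[0, 1)`.
#' @param truncation Length-2 numeric, the hard support of the IBI
#'   distribution in seconds. The default `(0.55, 1.25)` keeps essentially
#'   all draws inside the downstream plausibility filter when
#'   `mean +- 3 sd` fits in it.
#'
#' @return An object of class `ibi_state_model`.
#' @export
#' @examples
#' m <- ibi_state_model()
#' sample_ibis(m, "NP", duration = 30, seed = 1)
ibi_state_model <- function(means = c(LP = 0.90, NP = 0.80, HP = 0.70),
                            sds = c(LP = 0.04, NP = 0.04, HP = 0.04),
                            rho = 0.3,
                            truncation = c(0.55, 1.25)) {
  lv <- stress_levels()
  if (length(sds) == 1L) sds <- setNames(rep(sds, 3L), lv)
  if (!all(lv %in% names(means)) || !all(lv %in% names(sds))) {
    stopf("`means` and `sds` must be named with all of %s",
          paste(lv, collapse = ", "))
  }
  means <- means[lv]; sds <- sds[lv]
  if (any(means <= 0) || any(sds < 0)) stopf("means must be > 0 and sds >= 0")
  if (rho < 0 || rho >= 1) stopf("`rho` must lie in [0, 1)")
  if (truncation[1] >= truncation[2]) stopf("invalid truncation interval")
  out_of_band <- means - 3 * sds < truncation[1] | means + 3 * sds > truncation[2]
  if (any(out_of_band)) {
    warning("mean +- 3 sd leaves the truncation band for state(s): ",
            paste(lv[out_of_band], collapse = ", "))
  }
  structure(
    list(means = means, sds = sds, rho = rho, truncation = truncation,
         family = "truncated-gaussian-ar1"),
    class = "ibi_state_model"
  )
}

#' Sample interbeat intervals for one stress state
#'
#' Draws IBIs from the state's truncated Gaussian AR(1) process until their
#' cumulative sum reaches `duration`. Out-of-band draws are rejected and
#' redrawn, so every returned interval lies inside the model's truncation
#' band.
#'
#' @param model An [ibi_state_model()].
#' @param label One stress level.
#' @param duration Target span in seconds (> 0); the cumulative sum of the
#'   returned intervals is the smallest partial sum `>= duration`.
#' @param seed Integer seed; fixed seed gives an identical sequence.
#'
#' @return Numeric vector of IBIs in seconds.
#' @export
sample_ibis <- function(model, label, duration, seed = 1L) {
  stopifnot(inherits(model, "ibi_state_model"))
  label <- as.character(as_stress_factor(label))
  if (!is.finite(duration) || duration <= 0) stopf("`duration` must be > 0")
  mu <- model$means[[label]]
  sigma <- model$sds[[label]]
  if (mu >= duration) stopf("state mean IBI (%.3f s) must be below `duration`", mu)
  rho <- model$rho
  lo <- model$truncation[1]; hi <- model$truncation[2]

  if (sigma == 0) {
    n <- ceiling(duration / mu)
    if (n * mu < duration) n <- n + 1L   # guard against float shortfall
    return(rep(mu, n))
  }

  draw_trunc <- function(center, scale) {
    for (i in 1:100) {
      x <- rnorm(1L, center, scale)
      if (x >= lo && x <= hi) return(x)
    }
    min(max(center, lo), hi)
  }

  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  on.exit(.restore_seed(old), add = TRUE)

  innov_sd <- sigma * sqrt(1 - rho^2)
  out <- numeric(0)
  x <- draw_trunc(mu, sigma)
  total <- x
  out <- x
  while (total < duration) {
    center <- mu + rho * (x - mu)
    x <- draw_trunc(center, innov_sd)
    out <- c(out, x)
    total <- total + x
  }
  out
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
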