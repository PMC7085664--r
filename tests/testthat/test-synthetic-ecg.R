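test_that("default timeline reproduces the six recorded protocol phases", {
  tl <- default_timeline()
  expect_equal(nrow(tl), 6)
  expect_equal(sum(tl$duration), 1680)
  expect_equal(tl$duration, c(330, 330, 180, 330, 180, 330))
  expect_equal(as.character(tl$label[1]), "LP")
  expect_equal(as.character(tl$label[c(3, 5)]), c("HP", "HP"))
  # contiguity from 0
  expect_equal(tl$start[1], 0)
  expect_equal(tl$start[-1], tl$end[-6])
})

test_that("zero-variance IBI sampling returns exact constant intervals", {
  m0 <- ibi_state_model(sds = c(LP = 0, NP = 0, HP = 0))
  iv <- sample_ibis(m0, "NP", duration = 8)
  expect_true(length(iv) %in% c(10L, 11L))
  expect_true(all(iv == 0.8))
  expect_gte(sum(iv), 8)
})

test_that("sampled IBIs recover the state distribution and are reproducible", {
  m <- ibi_state_model()
  iv <- sample_ibis(m, "NP", duration = 300, seed = 7)
  expect_gte(sum(iv), 300)
  expect_lt(abs(mean(iv) - 0.8), 0.01)
  expect_identical(iv, sample_ibis(m, "NP", duration = 300, seed = 7))
  # 3-standard-error distribution recovery at n >= 300
  for (lab in stress_levels()) {
    iv <- sample_ibis(m, lab, duration = 300, seed = 13)
    n <- length(iv)
    expect_gte(n, 300)
    se_mean <- m$sds[[lab]] / sqrt(n)
    expect_lt(abs(mean(iv) - m$means[[lab]]), 3 * se_mean)
    se_sd <- m$sds[[lab]] / sqrt(2 * (n - 1))
    expect_lt(abs(sd(iv) - m$sds[[lab]]), 3 * se_sd)
  }
})

test_that("invalid sampling requests are rejected", {
  m <- ibi_state_model()
  expect_error(sample_ibis(m, "NP", duration = 0))
  expect_error(sample_ibis(m, "NP", duration = 0.5), "mean")
  expect_error(ibi_state_model(rho = 1))
  expect_warning(ibi_state_model(sds = c(LP = 0.3, NP = 0.3, HP = 0.3)),
                 "truncation")
})

test_that("synthesized record has exact duration, grid-aligned constant beats", {
  syn <- fix_const_session()
  expect_equal(length(syn$record$samples), 60 * 500)
  expect_equal(unique(diff(round(syn$truth$beats$time * 500))), 400)
  full <- fix_full_session()
  expect_equal(length(full$record$samples), 1680 * 500)
  expect_equal(nrow(full$record$annotations), 6)
})

test_that("ground-truth IBIs are successive beat differences per phase", {
  full <- fix_full_session()
  for (ph in unique(full$truth$ibis$phase)) {
    b <- full$truth$beats$time[full$truth$beats$phase == ph]
    iv <- full$truth$ibis$ibi[full$truth$ibis$phase == ph]
    expect_equal(length(iv), length(b) - 1)
    expect_equal(iv, diff(b))
  }
  expect_true(all(diff(full$truth$beats$time) > 0))
})

test_that("sampling rate below 100 Hz is rejected", {
  expect_error(synthesize_ecg(session_timeline("a", 10, "NP"),
                              sampling_rate = 80), "100 Hz")
})

test_that("noise is additive, spectrally placed, and reproducible", {
  syn <- fix_var_session()
  # zero-amplitude spec is the identity
  z <- noise_spec(powerline_amp = 0, wander_amp = 0, white_sd = 0)
  expect_identical(add_noise(syn$record, z, seed = 1)$samples,
                   syn$record$samples)
  # pure powerline: FFT peak of the difference at 50 Hz
  p <- noise_spec(powerline_amp = 0.3, wander_amp = 0, white_sd = 0)
  noisy <- add_noise(syn$record, p, seed = 4)
  d <- noisy$samples - syn$record$samples
  spec <- Mod(fft(d))[1:(length(d) %/% 2)]
  f <- (seq_along(spec) - 1) * 500 / length(d)
  expect_equal(f[which.max(spec)], 50, tolerance = 0.01)
  # determinism
  full_spec <- noise_spec()
  expect_identical(add_noise(syn$record, full_spec, seed = 9)$samples,
                   add_noise(syn$record, full_spec, seed = 9)$samples)
})

test_that("label separation knob puts the three states in distinct bin modes", {
  segs <- fix_segments()
  sc <- default_bin_scheme()
  modes <- vapply(stress_levels(), function(lv) {
    iv <- unlist(lapply(segs, function(s) {
      s$ibi[as.character(s$label) == lv & s$ibi >= 0.6 & s$ibi <= 1.2]
    }))
    which.max(tabulate(findInterval(iv, sc$breakpoints,
                                    rightmost.closed = TRUE), sc$n))
  }, integer(1))
  expect_equal(length(unique(modes)), 3)
  # shorter IBIs under higher stress: modes ordered LP > NP > HP
  expect_true(modes[["LP"]] > modes[["NP"]])
  expect_true(modes[["NP"]] > modes[["HP"]])
})

test_that("ECG and IBI file dialects round-trip", {
  syn <- fix_const_session()
  tmp <- tempfile(fileext = ".csv")
  write_ecg_csv(syn$record, tmp)
  back <- read_ecg_csv(tmp)
  expect_equal(back$samples, syn$record$samples, tolerance = 1e-12)
  expect_equal(back$sampling_rate, 500)
  ser <- ibi_series(c(1, 1.8), c(0.8, 0.8), "NP")
  tmp2 <- tempfile(fileext = ".csv")
  write_ibi_csv(ser, tmp2)
  back2 <- read_ibi_csv(tmp2)
  expect_equal(back2$ibi, ser$ibi)
  expect_equal(as.character(back2$label), as.character(ser$label))
  unlink(c(tmp, paste0(tmp, ".json"), tmp2))
})
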