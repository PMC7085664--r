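test_that("classification metrics match a hand-counted confusion matrix", {
  truth <- c("LP", "LP", "LP", "NP", "NP", "HP", "HP", "HP", "HP")
  pred  <- c("LP", "LP", "NP", "NP", "HP", "HP", "HP", "LP", "HP")
  m <- classification_metrics(truth, pred)
  expect_equal(unclass(m$confusion),
               matrix(c(2, 1, 0,
                        0, 1, 1,
                        1, 0, 3), 3, byrow = TRUE,
                      dimnames = list(truth = stress_levels(),
                                      predicted = stress_levels())),
               ignore_attr = FALSE)
  expect_equal(m$accuracy, 6 / 9)
  expect_equal(unname(m$sensitivity), c(2 / 3, 1 / 2, 3 / 4))
  expect_equal(unname(m$specificity), c(5 / 6, 6 / 7, 4 / 5))
  # prevalence-weighted sensitivities reproduce the accuracy
  prev <- rowSums(m$confusion) / sum(m$confusion)
  expect_equal(sum(prev * m$sensitivity), m$accuracy)
  # perfect and constant predictors
  p <- classification_metrics(truth, truth)
  expect_equal(p$accuracy, 1)
  expect_true(all(p$confusion[upper.tri(p$confusion)] == 0))
  bal <- rep(stress_levels(), each = 4)
  expect_equal(classification_metrics(bal, rep("NP", 12))$accuracy, 1 / 3)
  expect_error(classification_metrics(truth, pred[-1]), "lengths")
})

test_that("rsd is the coefficient of variation with its worked value", {
  expect_equal(rsd(rep(0.77, 50)), 0)
  expect_equal(rsd(c(0.9, 1.0)), sqrt(((-0.05)^2 + 0.05^2) / 1) / 0.95)
  expect_equal(rsd(c(0.9, 1.0)), 0.0744323, tolerance = 1e-6)
  x <- c(0.8, 0.85, 0.92)
  expect_equal(rsd(3 * x), rsd(x))
  expect_error(rsd(0.9), "two")
  expect_error(rsd(c(-1, 1)), "positive")
  set.seed(77)
  for (i in 1:20) {
    x <- runif(sample(2:60, 1), 0.2, 1)
    expect_equal(rsd(x), oracle_rsd(x), tolerance = 1e-12)
  }
})

small_segments <- function(n_per = 50, seed = 5) {
  mdl <- ibi_state_model()
  lapply(seq_along(stress_levels()), function(k) {
    lv <- stress_levels()[k]
    iv <- sample_ibis(mdl, lv, duration = n_per, seed = seed + k)
    t0 <- (k - 1) * 200
    ibi_series(t0 + cumsum(c(0, iv[-length(iv)])), iv, lv,
               segment_start = t0, segment_end = t0 + sum(iv) + 1)
  })
}

test_that("repeat_train records one seeded accuracy per repeat", {
  ds <- build_dataset(small_segments(), m = 16)
  cfg <- cnn_config(epochs = 2)
  run <- repeat_train(ds, cfg, repeats = 3, base_seed = 10)
  expect_length(run$accuracies, 3)
  expect_equal(run$seeds, 11:13)
  expect_true(all(run$accuracies >= 0 & run$accuracies <= 1))
  # identical seeds for all repeats collapse the spread to zero
  same <- repeat_train(ds, cfg, repeats = 2, seeds = c(7L, 7L))
  expect_equal(rsd(same$accuracies + 1e-12), 0, tolerance = 1e-9)
  expect_equal(same$accuracies[1], same$accuracies[2])
  # any single repeat reproducible in isolation from its recorded seed
  solo <- repeat_train(ds, cfg, repeats = 1, seeds = run$seeds[2])
  expect_equal(solo$accuracies, run$accuracies[2])
})

test_that("the m-sweep reports ordered entries and a smallest-tie best m", {
  segs <- small_segments(n_per = 40)
  sw <- sweep_m(segs, m_values = c(16, 18), repeats = 2,
                config = cnn_config(epochs = 2), base_seed = 3)
  expect_equal(sw$entries$m, c(16, 18))
  expect_true(all(sw$entries$rsd >= 0))
  expect_length(sw$runs[["16"]]$accuracies, 2)
  expect_equal(sw$best_m,
               sw$entries$m[which.max(sw$entries$mean_accuracy)])
  # infeasible m values are skipped with a warning
  expect_warning(
    sw2 <- sweep_m(segs, m_values = c(16, 60), repeats = 2,
                   config = cnn_config(epochs = 1), base_seed = 3),
    "skipped")
  expect_equal(sw2$entries$m, 16)
})

test_that("sweep report round-trips through CSV and writes a plot", {
  segs <- small_segments(n_per = 40)
  sw <- sweep_m(segs, m_values = c(16, 17), repeats = 2,
                config = cnn_config(epochs = 1), base_seed = 9)
  dir <- tempfile()
  paths <- sweep_report(sw, dir)
  got <- read.csv(file.path(dir, "sweep.csv"))
  expect_equal(nrow(got), 2)
  expect_equal(got$mean_accuracy, sw$entries$mean_accuracy)
  expect_equal(got$rsd, sw$entries$rsd)
  expect_true(file.exists(file.path(dir, "sweep.png")))
  expect_gt(file.size(file.path(dir, "sweep.png")), 0)
  js <- jsonlite::read_json(file.path(dir, "sweep.json"),
                            simplifyVector = TRUE)
  expect_equal(js$best_m, sw$best_m)
  unlink(dir, recursive = TRUE)
})
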