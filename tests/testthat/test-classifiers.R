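# small, well-separated picture dataset for fast training tests
small_dataset <- function(n_per = 60, m = 16, seed = 5) {
  mdl <- ibi_state_model()
  segs <- lapply(seq_along(stress_levels()), function(k) {
    lv <- stress_levels()[k]
    iv <- sample_ibis(mdl, lv, duration = n_per, seed = seed + k)
    t0 <- (k - 1) * 200
    ibi_series(t0 + cumsum(c(0, iv[-length(iv)])), iv, lv,
               segment_start = t0, segment_end = t0 + sum(iv) + 1)
  })
  build_dataset(segs, m = m)
}

test_that("CNN architecture matches the configured layer chain", {
  model <- build_cnn(cnn_config(input_shape = c(28, 28), seed = 1))
  p <- model$params
  expect_equal(dim(p$conv1$W), c(25, 6))
  expect_equal(dim(p$conv2$W), c(25 * 6, 16))
  expect_equal(dim(p$conv3$W), c(25 * 16, 120))
  expect_equal(model$shapes$pool1, c(14, 14))
  expect_equal(model$shapes$pool2, c(7, 7))
  expect_equal(model$shapes$flat, 7 * 7 * 120)
  expect_equal(dim(p$fc1$W), c(5880, 120))
  expect_equal(dim(p$fc2$W), c(120, 84))
  expect_equal(dim(p$fc3$W), c(84, 3))
  # parameter count is a pure function of shape, not seed
  expect_equal(n_params(build_cnn(cnn_config(seed = 99))$params),
               n_params(p))
  # forward pass gives 3 outputs per picture
  x <- array(0, c(28, 28, 1, 2))
  expect_equal(dim(ibipics:::cnn_forward(model, x)$logits), c(2, 3))
  expect_error(build_cnn(cnn_config(input_shape = c(28, 8))), "16")
})

test_that("CNN gradients agree with finite differences", {
  cfg <- cnn_config(input_shape = c(16, 16), seed = 7)
  model <- build_cnn(cfg)
  set.seed(8)
  x <- array(runif(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  y <- c(1L, 3L)
  fw <- ibipics:::cnn_forward(model, x, y, need_grads = TRUE)
  eps <- 1e-5
  set.seed(9)
  for (ln in c("conv1", "conv3", "fc1", "fc3")) {
    W <- model$params[[ln]]$W
    for (idx in sample(length(W), 4)) {
      mp <- model; mp$params[[ln]]$W[idx] <- W[idx] + eps
      mm <- model; mm$params[[ln]]$W[idx] <- W[idx] - eps
      lp <- ibipics:::softmax_ce(ibipics:::cnn_forward(mp, x)$logits, y)$loss
      lm <- ibipics:::softmax_ce(ibipics:::cnn_forward(mm, x)$logits, y)$loss
      num <- (lp - lm) / (2 * eps)
      expect_equal(fw$grads[[ln]]$W[idx], num, tolerance = 1e-4)
    }
  }
})

test_that("CNN separates well-separated synthetic states and is seeded", {
  ds <- split_chronological(small_dataset(), seed = 2)
  cfg <- cnn_config(epochs = 4, seed = 11)
  res <- train_cnn(ds, cfg)
  expect_gte(res$accuracy[["test"]], 0.9)
  # training loss trends down (single-epoch jitter tolerated)
  h <- res$history
  expect_lt(h[length(h)], h[1] + 1e-9)
  # accuracy from the confusion matrix equals the reported test accuracy
  expect_equal(sum(diag(res$confusion)) / sum(res$confusion),
               unname(res$accuracy[["test"]]))
  # same seed, same result
  res2 <- train_cnn(ds, cfg)
  expect_identical(res$accuracy, res2$accuracy)
})

test_that("degenerate datasets are rejected by the CNN trainer", {
  ds <- small_dataset()
  expect_error(train_cnn(ds), "split")
  ds1 <- split_chronological(ds, seed = 1)
  ds1$split[ds1$meta$label == "HP" & ds1$split == "test"] <- "validation"
  expect_error(train_cnn(ds1, cnn_config(epochs = 1)), "absent")
})

test_that("ANN reaches the separable limit and respects its architecture", {
  set.seed(4)
  n <- 60
  ft <- tibble::tibble(
    mean_ibi = rep(c(0.9, 0.8, 0.7), each = n),
    sdnn = rep(0.04, 3 * n) + runif(3 * n, 0, 1e-4),
    rmssd = rep(0.05, 3 * n) + runif(3 * n, 0, 1e-4),
    label = rep(stress_levels(), each = n)
  )
  res <- train_ann(ft, ann_config(seed = 6))
  expect_equal(unname(res$accuracy[["test"]]), 1.0)
  model <- res$model
  expect_equal(dim(model$params$h$W), c(3, 15))
  expect_equal(dim(model$params$o$W), c(15, 3))
  h <- res$history
  expect_lt(mean(tail(h, 5)), mean(head(h, 5)))
  # determinism: identical split and accuracies under the same seed
  res2 <- train_ann(ft, ann_config(seed = 6))
  expect_identical(res$accuracy, res2$accuracy)
  expect_identical(res$model$split, res2$model$split)
  # non-finite features rejected
  bad <- ft; bad$sdnn[1] <- NA
  expect_error(train_ann(bad), "finite")
})

test_that("ANN standardization comes from training-split statistics", {
  segs <- fix_segments()
  ft <- feature_table(lapply(segs, segment_windows))
  res <- train_ann(ft, ann_config(seed = 2))
  tr <- res$model$split == "train"
  X <- as.matrix(ft[tr, c("mean_ibi", "sdnn", "rmssd")])
  expect_equal(unname(res$model$center), unname(colMeans(X)))
  expect_gte(res$accuracy[["test"]], 0.8)
})
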