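test_that("the default bin scheme is the printed 28-cell partition", {
  sc <- default_bin_scheme()
  expect_equal(sc$n, 28)
  expect_equal(sc$breakpoints[1:2], c(0.6, 0.625))
  expect_equal(tail(sc$breakpoints, 2), c(1.175, 1.2))
  w <- diff(sc$breakpoints)
  expect_equal(w[1:4], rep(0.025, 4))
  expect_equal(w[5:24], rep(0.02, 20))
  expect_equal(w[25:28], rep(0.025, 4))
})

test_that("one-hot encoding places boundary values in the right cells", {
  sc <- default_bin_scheme()
  expect_equal(which(encode_ibi(0.70, sc) == 1), 5)   # [0.7, 0.72)
  expect_equal(which(encode_ibi(1.2, sc) == 1), 28)   # closed last cell
  expect_equal(which(encode_ibi(0.6, sc) == 1), 1)
  expect_equal(which(encode_ibi(0.625, sc) == 1), 2)  # right-hand cell
  expect_equal(sum(encode_ibi(0.834, sc)), 1)
  expect_error(encode_ibi(0.5, sc), "outside")
  expect_error(encode_ibi(1.21, sc), "outside")
})

test_that("windows become N x m one-hot pictures", {
  sc <- default_bin_scheme()
  pic <- encode_window(runif(28, 0.6, 1.2), sc, label = "NP")
  expect_equal(dim(pic), c(28, 28))
  expect_true(all(colSums(unclass(pic)) == 1))
  # constant input concentrates all mass on one row
  pc <- encode_window(rep(0.8, 10), sc, label = "LP")
  expect_equal(rowSums(unclass(pc))[10], 10)  # [0.8, 0.82) is cell 10
  expect_equal(sum(unclass(pc)), 10)
})

test_that("encode-decode recovers every IBI within its bin width", {
  sc <- default_bin_scheme()
  set.seed(42)
  x <- runif(500, 0.6, 1.2)
  pic <- encode_window(x, sc)
  back <- decode_picture(pic, sc)
  expect_true(all(abs(back - x) <= 0.025 / 2 + 1e-12))
})

test_that("PNG round trip is lossless with the declared polarity", {
  sc <- default_bin_scheme()
  pic <- encode_window(c(0.61, 0.8, 1.2), sc, label = "HP")
  path <- tempfile(fileext = ".png")
  picture_to_image(pic, path)
  img <- png::readPNG(path)
  expect_equal(dim(img)[1:2], c(28, 3))
  expect_equal(img[1, 1], 1)    # 0.61 -> first cell -> top row white
  back <- image_to_picture(path)
  expect_equal(unclass(back)[, ], unclass(pic)[, ])
  # non-binary image rejected
  gray <- tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 4, 4), gray)
  expect_error(image_to_picture(gray), "binary")
  unlink(c(path, gray))
})

test_that("dataset window counts and label purity hold", {
  mk_seg <- function(n, label, t0 = 0) {
    ibi_series(t0 + seq_len(n) * 0.8, rep(0.8, n), label,
               segment_start = t0, segment_end = t0 + n * 0.8 + 1)
  }
  ds <- build_dataset(list(mk_seg(100, "LP")), m = 28)
  expect_length(ds$pictures, 73)
  expect_warning(build_dataset(list(mk_seg(27, "LP")), m = 28), "skipped")
  ds2 <- build_dataset(list(mk_seg(40, "LP"), mk_seg(40, "NP", t0 = 100),
                            mk_seg(40, "HP", t0 = 200)), m = 10, stride = 5)
  expect_length(ds2$pictures, 3 * 7)
  labs <- vapply(ds2$pictures, function(p) attr(p, "label"), character(1))
  expect_equal(labs, as.character(ds2$meta$label))
  # windows never straddle segments: per-segment counts independent
  expect_equal(unname(table(ds2$meta$segment)), rep(7L, 3),
               ignore_attr = TRUE)
})

test_that("chronological split honours the 70/15/15 odd rule and ordering", {
  mk_seg <- function(n, label, t0 = 0) {
    ibi_series(t0 + seq_len(n) * 0.8, rep(0.8, n), label,
               segment_start = t0, segment_end = t0 + n * 0.8 + 1)
  }
  # 10 pictures of one class -> 7 train, 2 validation, 1 test
  ds <- build_dataset(list(mk_seg(12, "LP"), mk_seg(12, "NP", t0 = 50),
                           mk_seg(12, "HP", t0 = 100)), m = 3)
  ds <- split_chronological(ds, seed = 3)
  for (lv in stress_levels()) {
    tab <- table(ds$split[ds$meta$label == lv])
    expect_equal(unname(tab[c("train", "validation", "test")]),
                 c(7L, 2L, 1L), ignore_attr = TRUE)
  }
  # identical on re-run with the same seed
  ds_b <- split_chronological(ds, seed = 3)
  expect_identical(ds$split, ds_b$split)
  # all validation/test pictures chronologically at/after the last train one
  for (lv in stress_levels()) {
    idx <- ds$meta$label == lv
    last_train <- max(ds$meta$order[idx & ds$split == "train"])
    expect_true(all(ds$meta$order[idx & ds$split != "train"] > last_train))
  }
  expect_error(split_chronological(build_dataset(list(mk_seg(4, "LP"),
                                                      mk_seg(12, "NP", 50),
                                                      mk_seg(12, "HP", 100)),
                                                 m = 3), seed = 1),
               "at least 3")
})

test_that("split proportions stay within one picture of 70% per class", {
  segs <- fix_segments()
  ds <- split_chronological(build_dataset(segs, m = 28), seed = 1)
  for (lv in stress_levels()) {
    n <- sum(ds$meta$label == lv)
    n_train <- sum(ds$meta$label == lv & ds$split == "train")
    expect_lte(abs(n_train - 0.7 * n), 1)
  }
})
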