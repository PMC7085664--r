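#' CNN configuration
#'
#' The 8-layer architecture used for picture classification: three
#' convolution layers of 6, 16 and 120 filters (each a 5x5 kernel,
#' zero-padded "same"), a 2x2 max-pooling layer after each of the first
#' two convolutions, and fully connected layers of depth 120, 84 and 3.
#' The "same" padding keeps the 5x5/2x2 chain valid for every picture
#' width in the sweep range (16--47 IBIs per picture).
#'
#' @param input_shape Length-2 integer `c(N, m)`: picture rows (bins) and
#'   columns (IBIs per picture). Both must be at least 16.
#' @param filters Filter counts of the three convolution layers.
#' @param kernel Convolution kernel side (5).
#' @param dense Depths of the fully connected layers; the last must equal
#'   the number of classes (3).
#' @param epochs,learning_rate,batch_size Training hyperparameters
#'   (Adam on softmax cross-entropy).
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(input_shape = c(28L, 28L),
                       filters = c(6L, 16L, 120L), kernel = 5L,
                       dense = c(120L, 84L, 3L),
                       epochs = 30L, learning_rate = 1e-3,
                       batch_size = 32L, seed = 1L) {
  if (dense[length(dense)] != 3L) stopf("final dense depth must be 3 (classes)")
  if (length(filters) != 3L || length(dense) != 3L) {
    stopf("expected 3 convolution layers and 3 dense layers")
  }
  structure(list(input_shape = as.integer(input_shape),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 dense = as.integer(dense), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' Build the picture-classification CNN
#'
#' Instantiates the layer chain conv(6, 5x5) -> pool(2x2) -> conv(16, 5x5)
#' -> pool(2x2) -> conv(120, 5x5) -> dense 120 -> dense 84 -> dense 3,
#' with ReLU after every convolution and hidden dense layer, and He-style
#' Gaussian weight initialization under the config seed. The architecture
#' (layer shapes, parameter count) is a pure function of the input shape
#' and config.
#'
#' @param config A [cnn_config()].
#' @return An object of class `cnn_model` with fields `params`, `config`,
#'   `shapes` and the im2col plans.
#' @export
build_cnn <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  N <- config$input_shape[1]
  m <- config$input_shape[2]
  k <- config$kernel
  if (N < 16L || m < 16L) {
    stopf("input %d x %d is below the supported minimum 16 x 16 for the 5x5/2x2 chain",
          N, m)
  }
  h1 <- N %/% 2L; w1 <- m %/% 2L       # after pool 1
  h2 <- h1 %/% 2L; w2 <- w1 %/% 2L     # after pool 2
  flat <- h2 * w2 * config$filters[3]

  old <- .Random.seed_exists()
  set.seed(config$seed)
  on.exit(.restore_seed(old), add = TRUE)
  init_w <- function(nin, nout) {
    matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  }
  f <- config$filters
  params <- list(
    conv1 = list(W = init_w(k * k * 1L, f[1]), b = numeric(f[1])),
    conv2 = list(W = init_w(k * k * f[1], f[2]), b = numeric(f[2])),
    conv3 = list(W = init_w(k * k * f[2], f[3]), b = numeric(f[3])),
    fc1 = list(W = init_w(flat, config$dense[1]), b = numeric(config$dense[1])),
    fc2 = list(W = init_w(config$dense[1], config$dense[2]),
               b = numeric(config$dense[2])),
    fc3 = list(W = init_w(config$dense[2], config$dense[3]),
               b = numeric(config$dense[3]))
  )
  structure(list(
    params = params,
    config = config,
    shapes = list(input = c(N, m), pool1 = c(h1, w1), pool2 = c(h2, w2),
                  flat = flat),
    prep1 = conv_prep(N, m, 1L, k),
    prep2 = conv_prep(h1, w1, f[1], k),
    prep3 = conv_prep(h2, w2, f[2], k)
  ), class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  s <- x$shapes
  f <- x$config$filters
  cat(sprintf(
    "<cnn_model> %dx%dx1 -> conv%d -> pool -> conv%d -> pool -> conv%d -> fc %s (%s parameters)\n",
    s$input[1], s$input[2], f[1], f[2], f[3],
    paste(x$config$dense, collapse = "-"),
    format(n_params(x$params), big.mark = ",")))
  invisible(x)
}

cnn_forward <- function(model, x, y_int = NULL, need_grads = FALSE) {
  p <- model$params
  B <- dim(x)[4]
  c1 <- conv_forward(x, p$conv1$W, p$conv1$b, model$prep1)
  r1 <- relu(c1$y)
  pl1 <- pool_forward(r1)
  c2 <- conv_forward(pl1$y, p$conv2$W, p$conv2$b, model$prep2)
  r2 <- relu(c2$y)
  pl2 <- pool_forward(r2)
  c3 <- conv_forward(pl2$y, p$conv3$W, p$conv3$b, model$prep3)
  r3 <- relu(c3$y)
  X <- t(matrix(r3, ncol = B))
  h1 <- relu(dense_forward(X, p$fc1$W, p$fc1$b))
  h2 <- relu(dense_forward(h1, p$fc2$W, p$fc2$b))
  logits <- dense_forward(h2, p$fc3$W, p$fc3$b)
  if (!need_grads) return(list(logits = logits))

  ce <- softmax_ce(logits, y_int)
  g3 <- ce$dlogits
  grads <- list()
  grads$fc3 <- list(W = crossprod(h2, g3), b = colSums(g3))
  g2 <- tcrossprod(g3, p$fc3$W) * (h2 > 0)
  grads$fc2 <- list(W = crossprod(h1, g2), b = colSums(g2))
  g1 <- tcrossprod(g2, p$fc2$W) * (h1 > 0)
  grads$fc1 <- list(W = crossprod(X, g1), b = colSums(g1))
  gX <- tcrossprod(g1, p$fc1$W)        # B x flat
  g_r3 <- array(t(gX), dim = dim(r3))
  g_r3 <- g_r3 * (r3 > 0)
  bc3 <- conv_backward(g_r3, p$conv3$W, c3, model$prep3, need_dx = TRUE)
  grads$conv3 <- list(W = bc3$dW, b = bc3$db)
  g_p2 <- pool_backward(bc3$dx, pl2)
  g_r2 <- g_p2 * (r2 > 0)
  bc2 <- conv_backward(g_r2, p$conv2$W, c2, model$prep2, need_dx = TRUE)
  grads$conv2 <- list(W = bc2$dW, b = bc2$db)
  g_p1 <- pool_backward(bc2$dx, pl1)
  g_r1 <- g_p1 * (r1 > 0)
  bc1 <- conv_backward(g_r1, p$conv1$W, c1, model$prep1, need_dx = FALSE)
  grads$conv1 <- list(W = bc1$dW, b = bc1$db)
  list(logits = logits, loss = ce$loss, grads = grads)
}

#' Predict stress classes for pictures
#'
#' @param object A trained `cnn_model`.
#' @param x Array `N x m x 1 x n` of pictures (see [dataset_tensors()]).
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Factor of predicted stress levels.
#' @export
predict.cnn_model <- function(object, x, batch_size = 256L, ...) {
  n <- dim(x)[4]
  out <- integer(n)
  for (i0 in seq(1L, n, by = batch_size)) {
    i1 <- min(n, i0 + batch_size - 1L)
    lg <- cnn_forward(object, x[, , , i0:i1, drop = FALSE])$logits
    out[i0:i1] <- max.col(lg, ties.method = "first")
  }
  factor(stress_levels()[out], levels = stress_levels())
}

#' Train the CNN on a split picture dataset
#'
#' Trains on the training split only, with mini-batch Adam on softmax
#' cross-entropy under the config seed (weight init, shuffling), then
#' reports accuracy on all three splits, the test-split confusion matrix
#' and per-class sensitivity/specificity. All three classes must be
#' present in every split.
#'
#' @param dataset A [split_chronological()] picture dataset.
#' @param config A [cnn_config()]; its `input_shape` is overridden by the
#'   dataset's picture shape.
#' @return A `train_result`: list with `model`, `accuracy` (named vector
#'   train/validation/test), `confusion`, `sensitivity`, `specificity`,
#'   `history` (per-epoch mean training loss), `seed`.
#' @export
train_cnn <- function(dataset, config = cnn_config()) {
  stopifnot(inherits(dataset, "picture_dataset"))
  if (all(is.na(dataset$split))) stopf("dataset has no split; run split_chronological() first")
  splits <- c("train", "validation", "test")
  tens <- lapply(splits, function(s) dataset_tensors(dataset, s))
  names(tens) <- splits
  for (s in splits) {
    present <- levels(tens[[s]]$y) %in% unique(as.character(tens[[s]]$y))
    if (!all(present)) {
      stopf("class %s absent from the %s split",
            paste(levels(tens[[s]]$y)[!present], collapse = ","), s)
    }
  }
  config$input_shape <- c(dataset$scheme$n, dataset$m)
  model <- build_cnn(config)

  xtr <- tens$train$x
  ytr <- as.integer(tens$train$y)
  n <- length(ytr)
  state <- adam_init(model$params)
  history <- numeric(config$epochs)

  old <- .Random.seed_exists()
  set.seed(config$seed + 1L)
  on.exit(.restore_seed(old), add = TRUE)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (i0 in seq(1L, n, by = config$batch_size)) {
      i1 <- min(n, i0 + config$batch_size - 1L)
      sel <- ord[i0:i1]
      fw <- cnn_forward(model, xtr[, , , sel, drop = FALSE], ytr[sel],
                        need_grads = TRUE)
      upd <- adam_step(model$params, fw$grads, state, config$learning_rate)
      model$params <- upd$params
      state <- upd$state
      losses <- c(losses, fw$loss)
    }
    history[ep] <- mean(losses)
  }

  acc <- vapply(splits, function(s) {
    mean(predict(model, tens[[s]]$x) == tens[[s]]$y)
  }, numeric(1))
  mets <- classification_metrics(tens$test$y, predict(model, tens$test$x))
  structure(list(model = model, accuracy = acc, confusion = mets$confusion,
                 sensitivity = mets$sensitivity,
                 specificity = mets$specificity,
                 history = history, seed = config$seed),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat("<train_result> accuracy:",
      paste(sprintf("%s %.3f", names(x$accuracy), x$accuracy), collapse = ", "),
      "\n")
  invisible(x)
}
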