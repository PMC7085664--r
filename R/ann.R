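#' ANN (baseline) configuration
#'
#' The 3-15-3 feed-forward network over the three time-domain HRV
#' features: 3 input nodes, one hidden layer of 15 neurons with a
#' hyperbolic-tangent sigmoid transfer function, and 3 linear output
#' nodes; the predicted class is the index of the maximal output.
#' Trained full-batch on softmax cross-entropy with Adam.
#'
#' @param hidden Hidden-layer width (15).
#' @param epochs Full-batch iterations.
#' @param learning_rate Adam step size.
#' @param seed Integer seed (initialization and data split).
#' @return An object of class `ann_config`.
#' @export
ann_config <- function(hidden = 15L, epochs = 500L, learning_rate = 0.02,
                       seed = 1L) {
  structure(list(inputs = 3L, hidden = as.integer(hidden), outputs = 3L,
                 hidden_transfer = "tanh", output_transfer = "linear",
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "ann_config")
}

#' Build the 3-15-3 feature network
#'
#' @param config An [ann_config()].
#' @return An object of class `ann_model` with Gaussian-initialized
#'   weights under the config seed.
#' @export
build_ann <- function(config = ann_config()) {
  stopifnot(inherits(config, "ann_config"))
  old <- .Random.seed_exists()
  set.seed(config$seed)
  on.exit(.restore_seed(old), add = TRUE)
  params <- list(
    h = list(W = matrix(rnorm(config$inputs * config$hidden, 0,
                              sqrt(1 / config$inputs)),
                        config$inputs, config$hidden),
             b = numeric(config$hidden)),
    o = list(W = matrix(rnorm(config$hidden * config$outputs, 0,
                              sqrt(1 / config$hidden)),
                        config$hidden, config$outputs),
             b = numeric(config$outputs))
  )
  structure(list(params = params, config = config,
                 center = NULL, scale = NULL),
            class = "ann_model")
}

ann_logits <- function(model, X) {
  h <- tanh(dense_forward(X, model$params$h$W, model$params$h$b))
  list(h = h, logits = dense_forward(h, model$params$o$W, model$params$o$b))
}

#' Predict stress classes from HRV features
#'
#' @param object A trained `ann_model`.
#' @param features Tibble/data frame with columns `mean_ibi`, `sdnn`,
#'   `rmssd` (or a 3-column numeric matrix in that order).
#' @param ... Unused.
#' @return Factor of predicted stress levels.
#' @export
predict.ann_model <- function(object, features, ...) {
  X <- ann_feature_matrix(features)
  X <- scale(X, center = object$center, scale = object$scale)
  lg <- ann_logits(object, X)$logits
  factor(stress_levels()[max.col(lg, ties.method = "first")],
         levels = stress_levels())
}

ann_feature_matrix <- function(features) {
  if (is.matrix(features)) {
    stopifnot(ncol(features) == 3L)
    X <- features
  } else {
    stopifnot(all(c("mean_ibi", "sdnn", "rmssd") %in% names(features)))
    X <- as.matrix(features[, c("mean_ibi", "sdnn", "rmssd")])
  }
  if (!all(is.finite(X))) stopf("non-finite feature values")
  X
}

#' Train the HRV-feature baseline network
#'
#' Randomly splits the feature table 70/15/15 into learning, validation
#' and test sets under the seed, standardizes features on training-split
#' statistics, and trains the 3-15-3 network full-batch. Reports the same
#' result structure as [train_cnn()].
#'
#' @param features A [feature_table()] with a `label` column.
#' @param config An [ann_config()].
#' @return A `train_result` (see [train_cnn()]) whose `model` also stores
#'   the standardization constants and split assignment.
#' @export
train_ann <- function(features, config = ann_config()) {
  X <- ann_feature_matrix(features)
  y <- as_stress_factor(features$label)
  if (anyNA(y)) stopf("features must carry stress labels")
  n <- nrow(X)
  if (n < 10L) stopf("too few feature rows (%d) to split 70/15/15", n)

  old <- .Random.seed_exists()
  set.seed(config$seed)
  on.exit(.restore_seed(old), add = TRUE)

  ord <- sample.int(n)
  n_train <- round(0.70 * n)
  n_val <- round(0.15 * n)
  split <- rep("test", n)
  split[ord[seq_len(n_train)]] <- "train"
  split[ord[n_train + seq_len(n_val)]] <- "validation"

  tr <- split == "train"
  center <- colMeans(X[tr, , drop = FALSE])
  scl <- apply(X[tr, , drop = FALSE], 2L, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = center, scale = scl)

  model <- build_ann(config)
  model$center <- center
  model$scale <- scl
  y_int <- as.integer(y)
  state <- adam_init(model$params)
  history <- numeric(config$epochs)
  Xtr <- Xs[tr, , drop = FALSE]
  ytr <- y_int[tr]
  for (ep in seq_len(config$epochs)) {
    fw <- ann_logits(model, Xtr)
    ce <- softmax_ce(fw$logits, ytr)
    g_o <- ce$dlogits
    grads <- list(
      o = list(W = crossprod(fw$h, g_o), b = colSums(g_o)),
      h = list(W = crossprod(Xtr, tcrossprod(g_o, model$params$o$W) * (1 - fw$h^2)),
               b = colSums(tcrossprod(g_o, model$params$o$W) * (1 - fw$h^2)))
    )
    upd <- adam_step(model$params, grads, state, config$learning_rate)
    model$params <- upd$params
    state <- upd$state
    history[ep] <- ce$loss
  }

  pred_all <- {
    lg <- ann_logits(model, Xs)$logits
    factor(stress_levels()[max.col(lg, ties.method = "first")],
           levels = stress_levels())
  }
  acc <- vapply(c(train = "train", validation = "validation", test = "test"),
                function(s) mean(pred_all[split == s] == y[split == s]),
                numeric(1))
  mets <- classification_metrics(y[split == "test"], pred_all[split == "test"])
  model$split <- split
  structure(list(model = model, accuracy = acc, confusion = mets$confusion,
                 sensitivity = mets$sensitivity,
                 specificity = mets$specificity,
                 history = history, seed = config$seed),
            class = "train_result")
}
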