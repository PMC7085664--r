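#' Multiclass classification metrics
#'
#' Confusion matrix (rows = true class, columns = predicted), overall
#' accuracy, and per-class sensitivity (true-positive rate,
#' `confusion[i,i] / row total`) and specificity (true-negative rate).
#'
#' @param truth,predicted Equal-length label vectors over the three
#'   stress levels.
#' @return List with `accuracy`, `confusion` (3x3 matrix), `sensitivity`,
#'   `specificity` (named numeric vectors).
#' @export
classification_metrics <- function(truth, predicted) {
  truth <- as_stress_factor(truth)
  predicted <- as_stress_factor(predicted)
  if (length(truth) != length(predicted)) {
    stopf("`truth` and `predicted` lengths differ")
  }
  cm <- table(truth = truth, predicted = predicted)
  cm <- unclass(cm)
  total <- sum(cm)
  sens <- diag(cm) / rowSums(cm)
  spec <- vapply(seq_len(nrow(cm)), function(i) {
    tn <- total - sum(cm[i, ]) - sum(cm[, i]) + cm[i, i]
    neg <- total - sum(cm[i, ])
    if (neg == 0) NA_real_ else tn / neg
  }, numeric(1))
  names(spec) <- rownames(cm)
  list(accuracy = sum(diag(cm)) / total, confusion = cm,
       sensitivity = sens, specificity = spec)
}

#' Relative standard deviation of repeated accuracies
#'
#' Coefficient of variation: the sample standard deviation (n-1
#' denominator) of the accuracies divided by their mean. Used to measure
#' the stability of a picture width over repeated trainings.
#'
#' @param accuracies Numeric vector (length >= 2, positive mean).
#' @return Dimensionless RSD.
#' @export
#' @examples
#' rsd(c(0.9, 1.0))  # 0.07443...
rsd <- function(accuracies) {
  if (length(accuracies) < 2L) stopf("`rsd` needs at least two values")
  m <- mean(accuracies)
  if (m <= 0) stopf("`rsd` needs a positive mean")
  sd(accuracies) / m
}

#' Repeatedly train the CNN and record its accuracy
#'
#' Runs `repeats` full trainings of the same dataset, repeat i using the
#' derived seed `base_seed + i` for both the validation/test re-halving
#' and the weight initialization/shuffling, and records the test-split
#' accuracy of each. The seed schedule is returned so any single repeat
#' is reproducible in isolation.
#'
#' @param dataset An unsplit (or split) [build_dataset()] result; the
#'   chronological split is re-drawn per repeat.
#' @param config A [cnn_config()].
#' @param repeats Number of repeats (50 for full fidelity; smaller values
#'   for desk-scale runs).
#' @param base_seed Integer base of the seed schedule.
#' @param accuracy_split Which split's accuracy to record (default
#'   `"test"`).
#' @param seeds Optional explicit seed vector overriding the schedule
#'   (length `repeats`); identical seeds give identical repeats and hence
#'   zero RSD.
#' @return List of class `repeat_run`: `accuracies`, `seeds`, `m`.
#' @export
repeat_train <- function(dataset, config = cnn_config(), repeats = 5L,
                         base_seed = 1L,
                         accuracy_split = c("test", "validation", "train"),
                         seeds = NULL) {
  accuracy_split <- match.arg(accuracy_split)
  seeds <- as.integer(seeds %||% (as.integer(base_seed) + seq_len(repeats)))
  stopifnot(length(seeds) == repeats)
  accs <- vapply(seeds, function(s) {
    ds <- split_chronological(dataset, seed = s)
    cfg <- config
    cfg$seed <- s
    train_cnn(ds, cfg)$accuracy[[accuracy_split]]
  }, numeric(1))
  structure(list(accuracies = accs, seeds = seeds, m = dataset$m,
                 accuracy_split = accuracy_split),
            class = "repeat_run")
}

#' Sweep the number of IBIs per picture
#'
#' For each candidate picture width m, builds the picture dataset,
#' repeat-trains the CNN, and records the mean accuracy and its relative
#' standard deviation — the analysis used to choose the best picture
#' width. The best m maximizes mean accuracy, ties going to the smaller m.
#'
#' @param segments Segmented IBI series as for [build_dataset()].
#' @param m_values Candidate picture widths (16--47 at full fidelity).
#' @param repeats Trainings per m.
#' @param config A [cnn_config()] (its `input_shape`/`seed` are managed by
#'   the sweep).
#' @param stride Dataset window stride.
#' @param scheme Bin scheme.
#' @param base_seed Base of the per-repeat seed schedule.
#' @return A `sweep_result`: list with `entries` (tibble `m`,
#'   `mean_accuracy`, `rsd`), `best_m`, `runs` (list of `repeat_run`).
#' @export
sweep_m <- function(segments, m_values = 16:47, repeats = 5L,
                    config = cnn_config(), stride = 1L,
                    scheme = default_bin_scheme(), base_seed = 1L) {
  runs <- list()
  rows <- list()
  for (m in m_values) {
    ds <- suppressWarnings(build_dataset(segments, m, stride, scheme))
    if (length(ds$pictures) < 10L) {
      warning(sprintf("m = %d infeasible (%d pictures); skipped",
                      m, length(ds$pictures)))
      next
    }
    run <- repeat_train(ds, config, repeats,
                        base_seed = as.integer(base_seed) + 100L * m)
    runs[[as.character(m)]] <- run
    rows[[as.character(m)]] <- tibble::tibble(
      m = m, mean_accuracy = mean(run$accuracies), rsd = rsd(run$accuracies))
  }
  entries <- do.call(rbind, rows)
  best <- entries$m[which.max(entries$mean_accuracy)]
  structure(list(entries = entries, best_m = best, runs = runs),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d picture widths, best m = %d\n",
              nrow(x$entries), x$best_m))
  print(x$entries)
  invisible(x)
}

#' Write sweep results to disk
#'
#' Emits a CSV in the standard layout (`m`, `mean_accuracy`, `rsd`), a
#' JSON summary including the per-repeat seed schedule and accuracies, and
#' a scatter plot of mean accuracy and RSD against m.
#'
#' @param result A [sweep_m()] result.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
sweep_report <- function(result, dir) {
  stopifnot(inherits(result, "sweep_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "sweep.csv")
  write.csv(result$entries, csv, row.names = FALSE)
  js <- file.path(dir, "sweep.json")
  jsonlite::write_json(
    list(best_m = result$best_m,
         entries = result$entries,
         runs = lapply(result$runs, function(r) {
           list(m = r$m, seeds = r$seeds, accuracies = r$accuracies)
         })),
    js, auto_unbox = TRUE, digits = NA)
  plot_path <- file.path(dir, "sweep.png")
  df <- result$entries
  long <- rbind(
    data.frame(m = df$m, value = df$mean_accuracy, metric = "mean accuracy"),
    data.frame(m = df$m, value = df$rsd, metric = "RSD")
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = m, y = value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "IBIs per picture (m)", y = NULL) +
    ggplot2::theme_minimal()
  grDevices::png(plot_path, width = 800, height = 600)
  print(p)
  grDevices::dev.off()
  invisible(c(csv = csv, json = js, plot = plot_path))
}
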