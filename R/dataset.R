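#' Build a labelled picture dataset from segmented IBI series
#'
#' Slides a window of `m` consecutive intervals (advancing by `stride`)
#' over each segment's plausibility-filtered IBI sequence and encodes every
#' window as a binary picture carrying the segment's label. Windows never
#' straddle segment boundaries; a segment with fewer than `m` in-range
#' intervals contributes no pictures (with a warning).
#'
#' @param segments A list of single-label [ibi_series()] in chronological
#'   order, e.g. from [session_segments()].
#' @param m Number of IBIs per picture.
#' @param stride Window step in intervals (default 1, maximal overlap).
#' @param scheme A [bin_scheme()].
#' @return An object of class `picture_dataset`: list with `pictures` (list
#'   of [encode_window()] pictures), `meta` (tibble: `segment`, `label`,
#'   `start_index`, `order`), `m`, `scheme`, and empty `split`.
#' @export
build_dataset <- function(segments, m, stride = 1L,
                          scheme = default_bin_scheme()) {
  stopifnot(is.list(segments), m >= 1L, stride >= 1L)
  pictures <- list()
  meta <- list()
  ord <- 0L
  for (s in seq_along(segments)) {
    seg <- filter_plausible(segments[[s]],
                            min(scheme$breakpoints), max(scheme$breakpoints))
    lab <- as.character(seg$label[1])
    n <- nrow(seg)
    if (n < m) {
      warning(sprintf("segment %d has %d in-range intervals (< m = %d); skipped",
                      s, n, m))
      next
    }
    starts <- seq(1L, n - m + 1L, by = stride)
    for (st in starts) {
      ord <- ord + 1L
      pictures[[ord]] <- encode_window(seg$ibi[st:(st + m - 1L)], scheme,
                                       label = lab, start_index = st)
      meta[[ord]] <- tibble::tibble(segment = s, label = lab,
                                    start_index = st, order = ord)
    }
  }
  meta <- if (length(meta)) do.call(rbind, meta) else
    tibble::tibble(segment = integer(), label = character(),
                   start_index = integer(), order = integer())
  meta$label <- as_stress_factor(meta$label)
  structure(list(pictures = pictures, meta = meta, m = m, scheme = scheme,
                 split = rep(NA_character_, nrow(meta))),
            class = "picture_dataset")
}

#' @export
print.picture_dataset <- function(x, ...) {
  cat(sprintf("<picture_dataset> %d pictures (%d x %d)",
              length(x$pictures), x$scheme$n, x$m))
  if (!all(is.na(x$split))) {
    tab <- table(x$split)
    cat(" | split:", paste(names(tab), tab, sep = "=", collapse = " "))
  }
  cat("\n")
  print(table(x$meta$label))
  invisible(x)
}

#' Chronological 70/15/15 split
#'
#' Within each class, the chronologically earliest `train_fraction` of
#' pictures become the training set; the remainder is randomly halved into
#' validation and test sets under `seed`, an odd remainder placing its
#' extra picture in validation. Every validation/test picture of a class is
#' therefore chronologically at or after that class's last training
#' picture.
#'
#' @param dataset A [build_dataset()] result.
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.70).
#' @param seed Integer seed for the validation/test halving.
#' @return The dataset with its `split` field filled with
#'   `"train" | "validation" | "test"`.
#' @export
split_chronological <- function(dataset, train_fraction = 0.70, seed = 1L) {
  stopifnot(inherits(dataset, "picture_dataset"))
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("`train_fraction` must be in (0, 1)")
  }
  split <- rep(NA_character_, nrow(dataset$meta))
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  on.exit(.restore_seed(old), add = TRUE)
  for (lv in levels(dataset$meta$label)) {
    idx <- which(dataset$meta$label == lv)
    if (!length(idx)) next
    if (length(idx) < 3L) {
      stopf("class %s has %d picture(s); at least 3 are needed to split",
            lv, length(idx))
    }
    idx <- idx[order(dataset$meta$order[idx])]
    n <- length(idx)
    n_train <- floor(n * train_fraction + 0.5)
    n_train <- min(max(n_train, 1L), n - 2L)
    rest <- idx[(n_train + 1L):n]
    n_val <- ceiling(length(rest) / 2)
    val <- sort(sample(rest, n_val))
    split[idx[1:n_train]] <- "train"
    split[val] <- "validation"
    split[setdiff(rest, val)] <- "test"
  }
  dataset$split <- split
  dataset
}

#' Stack a dataset split into a 4-d array for the CNN
#'
#' @param dataset A split [picture_dataset()].
#' @param which One of `"train"`, `"validation"`, `"test"`, or `"all"`.
#' @return List with `x` (array `N x m x 1 x n`) and `y` (stress factor).
#' @export
dataset_tensors <- function(dataset, which = "all") {
  sel <- if (identical(which, "all")) seq_along(dataset$pictures) else
    which(dataset$split == which)
  if (!length(sel)) stopf("no pictures in split '%s'", which)
  n <- dataset$scheme$n
  x <- array(0, c(n, dataset$m, 1L, length(sel)))
  for (i in seq_along(sel)) x[, , 1L, i] <- unclass(dataset$pictures[[sel[i]]])
  list(x = x, y = dataset$meta$label[sel])
}
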