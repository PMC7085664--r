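#' Bin scheme for one-hot IBI encoding
#'
#' An ordered set of breakpoints partitioning the plausibility range into N
#' half-open cells `[a, b)`, the last cell closed at the top, so both 0.6 s
#' and 1.2 s are encodable.
#'
#' @param breakpoints Strictly increasing numeric vector of cell edges in
#'   seconds (N + 1 values for N cells).
#' @return An object of class `bin_scheme` with fields `breakpoints` and `n`.
#' @export
bin_scheme <- function(breakpoints) {
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) < 2L || any(diff(breakpoints) <= 0)) {
    stopf("`breakpoints` must be strictly increasing with at least 2 values")
  }
  structure(list(breakpoints = breakpoints, n = length(breakpoints) - 1L),
            class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("<bin_scheme> %d cells spanning [%g, %g] s\n",
              x$n, min(x$breakpoints), max(x$breakpoints)))
  invisible(x)
}

#' The 28-cell IBI bin scheme
#'
#' The standard partition of the 0.6--1.2 s plausibility band into 28
#' cells: four cells of width 0.025 s over `[0.6, 0.7)`, twenty cells of
#' width 0.02 s over `[0.7, 1.1)`, and four cells of width 0.025 s over
#' `[1.1, 1.2]` (final cell closed).
#'
#' @return A [bin_scheme()] with `n = 28`.
#' @export
#' @examples
#' default_bin_scheme()$n  # 28
default_bin_scheme <- function() {
  bin_scheme(c(seq(600L, 675L, 25L), seq(700L, 1100L, 20L),
               seq(1125L, 1200L, 25L)) / 1000)
}

#' One-hot encode a single interbeat interval
#'
#' Maps an in-range IBI to a binary column vector of length N with a single
#' 1 at the cell containing it. Cells are half-open `[a, b)`; the top
#' endpoint belongs to the (closed) last cell. Out-of-range values are an
#' error — filter with [filter_plausible()] first.
#'
#' @param ibi Interval in seconds (scalar or vector).
#' @param scheme A [bin_scheme()].
#' @return For a scalar, an integer 0/1 vector of length `scheme$n`; for a
#'   vector input, an `n x length(ibi)` matrix of one-hot columns.
#' @export
#' @examples
#' which(encode_ibi(0.70, default_bin_scheme()) == 1)  # 5th cell, [0.7, 0.72)
encode_ibi <- function(ibi, scheme = default_bin_scheme()) {
  stopifnot(inherits(scheme, "bin_scheme"))
  idx <- bin_index(ibi, scheme)
  m <- matrix(0L, scheme$n, length(ibi))
  m[cbind(idx, seq_along(ibi))] <- 1L
  if (length(ibi) == 1L) as.integer(m) else m
}

bin_index <- function(ibi, scheme) {
  br <- scheme$breakpoints
  bad <- ibi < br[1] | ibi > br[length(br)]
  if (any(bad)) {
    stopf("IBI value(s) outside the scheme span [%g, %g]: %s",
          br[1], br[length(br)],
          paste(format(head(ibi[bad], 3)), collapse = ", "))
  }
  findInterval(ibi, br, rightmost.closed = TRUE)
}

#' Encode a window of consecutive IBIs as a binary picture
#'
#' Splices the one-hot column vectors of `m` consecutive intervals into an
#' `N x m` binary matrix: column j encodes the j-th interval; row 1 is the
#' shortest-IBI cell. Every column sums to exactly 1.
#'
#' @param ibis Numeric vector of `m` consecutive in-range intervals.
#' @param scheme A [bin_scheme()].
#' @param label Stress label of the window.
#' @param start_index Position of the first interval in its source series.
#' @return An object of class `encoded_picture`: the 0/1 integer matrix
#'   with attributes `label`, `start_index`, `m`.
#' @export
encode_window <- function(ibis, scheme = default_bin_scheme(), label = NA,
                          start_index = 1L) {
  if (length(ibis) < 1L) stopf("a picture needs at least one interval")
  mat <- encode_ibi(ibis, scheme)
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1L)
  structure(mat,
            label = if (is.na(label[1])) NA_character_ else
              as.character(as_stress_factor(label)),
            start_index = as.integer(start_index),
            m = ncol(mat),
            class = c("encoded_picture", "matrix", "array"))
}

#' Decode a picture back to interval midpoints
#'
#' Maps each column's hot cell to the cell midpoint, recovering each IBI to
#' within its bin width.
#'
#' @param pic An [encode_window()] picture.
#' @param scheme The [bin_scheme()] it was encoded under.
#' @return Numeric vector of bin-midpoint IBIs in seconds.
#' @export
decode_picture <- function(pic, scheme = default_bin_scheme()) {
  br <- scheme$breakpoints
  mids <- (br[-1] + br[-length(br)]) / 2
  mids[apply(unclass(pic), 2L, which.max)]
}

#' Write / read a picture as a lossless PNG image
#'
#' Hot cells render white (255), cold cells black (0); row 1 (the
#' shortest-IBI cell) is the top image row. The round trip
#' `image_to_picture(picture_to_image(p))` is exact.
#'
#' @param pic An [encode_window()] picture.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
picture_to_image <- function(pic, path) {
  stopifnot(inherits(pic, "encoded_picture"))
  png::writePNG(matrix(as.numeric(pic), nrow(pic), ncol(pic)), path)
  invisible(path)
}

#' @param label,start_index Metadata to attach on read (PNG carries none).
#' @rdname picture_to_image
#' @return For `image_to_picture`, the reconstructed `encoded_picture`.
#' @export
image_to_picture <- function(path, label = NA, start_index = 1L) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  vals <- round(img * 255)
  if (!all(vals %in% c(0, 255))) {
    stopf("image is not a binary picture (non-0/255 pixel values)")
  }
  mat <- matrix(as.integer(vals == 255), nrow(img), ncol(img))
  if (!all(colSums(mat) == 1L)) stopf("image columns are not one-hot")
  structure(mat, label = label, start_index = as.integer(start_index),
            m = ncol(mat),
            class = c("encoded_picture", "matrix", "array"))
}
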