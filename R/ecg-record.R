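#' ECG record container
#'
#' A uniformly sampled single-channel voltage series (amplitude-normalized,
#' arbitrary units) with its sampling rate and ordered, non-overlapping
#' phase annotations.
#'
#' @param samples Numeric vector of voltage samples.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param annotations A data frame with columns `start_sample`,
#'   `end_sample` (1-based, inclusive), `label` and optionally `name`;
#'   may be `NULL` for an unannotated record.
#'
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, sampling_rate, annotations = NULL) {
  if (!is.numeric(samples)) stopf("`samples` must be numeric")
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stopf("`sampling_rate` must be a positive number")
  }
  if (!is.null(annotations)) {
    annotations <- tibble::as_tibble(annotations)
    stopifnot(all(c("start_sample", "end_sample", "label") %in% names(annotations)))
    annotations$label <- as_stress_factor(annotations$label)
    if (nrow(annotations) > 1L) {
      ok <- all(diff(annotations$start_sample) > 0) &&
        all(annotations$start_sample[-1] > annotations$end_sample[-nrow(annotations)])
      if (!ok) stopf("annotations must be ordered and non-overlapping")
    }
  }
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         annotations = annotations),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.1f s), %d annotated phase(s)\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate,
              if (is.null(x$annotations)) 0L else nrow(x$annotations)))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

record_duration <- function(record) length(record$samples) / record$sampling_rate

record_times <- function(record) {
  (seq_along(record$samples) - 1) / record$sampling_rate
}

with_samples <- function(record, samples) {
  stopifnot(length(samples) == length(record$samples))
  record$samples <- as.numeric(samples)
  record
}
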