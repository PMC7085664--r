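#' Read and write the package's ECG file dialect
#'
#' An ECG record is written as a two-column CSV (`time_s`, `value`) plus a
#' JSON sidecar (`<path>.json`) carrying the sampling rate and phase
#' annotations; `read_ecg_csv()` reverses it exactly (sampling rate from
#' the sidecar, not inferred).
#'
#' @param record An [ecg_record()].
#' @param path CSV output path; the sidecar goes to `paste0(path, ".json")`.
#' @return `path` (write) or an [ecg_record()] (read).
#' @export
write_ecg_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  df <- data.frame(time_s = record_times(record), value = record$samples)
  write.csv(df, path, row.names = FALSE)
  side <- list(sampling_rate = record$sampling_rate)
  if (!is.null(record$annotations)) {
    ann <- record$annotations
    ann$label <- as.character(ann$label)
    side$annotations <- ann
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ecg_csv
#' @export
read_ecg_csv <- function(path) {
  df <- read.csv(path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stopf("missing sidecar %s", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  ann <- side$annotations
  ecg_record(df$value, side$sampling_rate, annotations = ann)
}

#' Read and write IBI series CSV
#'
#' Columns `onset_s`, `ibi_s`, `label`.
#'
#' @param ibis An [ibi_series()].
#' @param path CSV path.
#' @return `path` (write) or an [ibi_series()] (read).
#' @export
write_ibi_csv <- function(ibis, path) {
  stopifnot(inherits(ibis, "ibi_series"))
  write.csv(data.frame(onset_s = ibis$onset, ibi_s = ibis$ibi,
                       label = as.character(ibis$label)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ibi_csv
#' @export
read_ibi_csv <- function(path) {
  df <- read.csv(path)
  lab <- if (all(is.na(df$label))) NA else df$label
  ibi_series(df$onset_s, df$ibi_s, label = lab)
}

#' Write ground-truth beats as CSV
#'
#' Columns `time_s`, `phase`, `label` — the generator's exact beat times.
#'
#' @param truth The `truth` element of a [synthesize_ecg()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  write.csv(data.frame(time_s = truth$beats$time, phase = truth$beats$phase,
                       label = as.character(truth$beats$label)),
            path, row.names = FALSE)
  invisible(path)
}
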