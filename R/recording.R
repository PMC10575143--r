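#' Construct an EEG recording
#'
#' Container for a multichannel EEG time series: a channels x samples
#' amplitude matrix in microvolts, a sampling rate and ordered channel
#' labels.
#'
#' @param data numeric matrix, channels x samples (µV).
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector, one unique label per row of
#'   `data`; defaults to `"C1"`, `"C2"`, ...
#' @param start_time seconds offset of the first sample (metadata only).
#' @return an object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(512), 2, 256), fs = 128)
eeg_recording <- function(data, fs, channel_labels = NULL, start_time = 0) {
  data <- as.matrix(data)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  if (is.null(channel_labels))
    channel_labels <- paste0("C", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop("channel_labels must match the number of channels", call. = FALSE)
  if (anyDuplicated(channel_labels))
    stop("channel_labels must be unique", call. = FALSE)
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 start_time = start_time),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Construct an annotation table of labelled intervals
#'
#' Intervals are half-open `[start_s, end_s)` in seconds from recording
#' start; `label` is 0 for interictal (healthy period) and 1 for ictal
#' (seizure period).
#'
#' @param start_s,end_s numeric vectors of interval bounds (s).
#' @param label integer vector in `{0, 1}`.
#' @return a `data.frame` of class `annotation_table`.
#' @export
annotation_table <- function(start_s, end_s, label) {
  ann <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                    label = as.integer(label))
  if (any(ann$start_s >= ann$end_s))
    stop("annotation intervals need start_s < end_s", call. = FALSE)
  if (!all(ann$label %in% c(0L, 1L)))
    stop("annotation labels must be 0 (interictal) or 1 (ictal)", call. = FALSE)
  ict <- ann[ann$label == 1L, , drop = FALSE]
  if (nrow(ict) > 1L) {
    o <- order(ict$start_s)
    if (any(ict$start_s[o][-1L] < ict$end_s[o][-nrow(ict)]))
      stop("ictal intervals must not overlap", call. = FALSE)
  }
  class(ann) <- c("annotation_table", "data.frame")
  ann
}

#' Read an annotation CSV
#'
#' Expects a header `start_s,end_s,label`.
#'
#' @param path path to the CSV file.
#' @return an [annotation_table()].
#' @export
read_annotations <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(tab)))
    stop("annotation CSV must have columns start_s,end_s,label", call. = FALSE)
  annotation_table(tab$start_s, tab$end_s, tab$label)
}

#' Construct a labelled epoch
#'
#' One fixed-duration multichannel window cut from a recording.
#'
#' @param data numeric matrix, channels x samples (µV).
#' @param label 0 (interictal) or 1 (ictal).
#' @param fs sampling rate in Hz.
#' @param source_id identifier of the source recording.
#' @param index ordinal of the epoch within its source.
#' @return an object of class `epoch`.
#' @export
epoch <- function(data, label, fs, source_id = "epoch", index = 1L) {
  data <- as.matrix(data)
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) stop("epoch label must be 0 or 1", call. = FALSE)
  structure(list(data = data, label = label, fs = fs,
                 source_id = source_id, index = as.integer(index)),
            class = "epoch")
}

#' @export
print.epoch <- function(x, ...) {
  cat(sprintf("<epoch %s#%d> %d ch x %d samples @ %g Hz, label %d\n",
              x$source_id, x$index, nrow(x$data), ncol(x$data), x$fs, x$label))
  invisible(x)
}

epoch_labels <- function(epochs) vapply(epochs, function(e) e$label, integer(1))
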