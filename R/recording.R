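#' Multichannel EEG recording container
#'
#' A lightweight S3 container for one continuous EEG recording: a channel x
#' sample matrix in microvolts plus sampling rate, channel names, event
#' intervals and subject/group metadata. Sample indices are 0-based and event
#' intervals are half-open `[onset, offset)`, in samples.
#'
#' @param data Numeric channel x sample matrix (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of `data`.
#' @param events Data frame with columns `onset`, `offset` (0-based sample
#'   indices, half-open) and `kind` (`"MI"` or `"baseline"`). May have 0 rows.
#' @param subject_id Subject identifier string.
#' @param recording_id Recording identifier string.
#' @param label Group label: 0 = healthy, 1 = impaired.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names, events = NULL,
                          subject_id = "S1", recording_id = "R1", label = 0L) {
  stopifnot(is.matrix(data), is.numeric(data))
  stopifnot(length(channel_names) == nrow(data))
  stopifnot(fs > 0)
  stopifnot(label %in% c(0L, 1L))
  if (is.null(events)) {
    events <- data.frame(onset = integer(0), offset = integer(0),
                         kind = character(0), stringsAsFactors = FALSE)
  }
  events <- as.data.frame(events)
  stopifnot(all(c("onset", "offset", "kind") %in% names(events)))
  if (nrow(events)) {
    stopifnot(all(events$onset < events$offset),
              all(events$offset <= ncol(data)),
              all(events$onset >= 0))
    ev <- events[order(events$onset), , drop = FALSE]
    if (nrow(ev) > 1 && any(ev$onset[-1] < ev$offset[-nrow(ev)])) {
      stop("event intervals must be non-overlapping")
    }
  }
  structure(
    list(data = data, fs = fs,
         channel_names = as.character(channel_names),
         events = events,
         subject_id = as.character(subject_id),
         recording_id = as.character(recording_id),
         label = as.integer(label)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording %s/%s: %d ch x %d samples @ %g Hz, label=%d, %d events>\n",
              x$subject_id, x$recording_id, nrow(x$data), ncol(x$data),
              x$fs, x$label, nrow(x$events)))
  invisible(x)
}

#' One-second epoch window
#'
#' An 11 x 125 (channels x samples) matrix with provenance metadata. Windows
#' are produced by [segment_windows()] and consumed by the quality-control,
#' normalization and feature stages.
#'
#' @param data Numeric channel x sample matrix (one second of signal).
#' @param subject_id,recording_id Provenance identifiers.
#' @param label Group label 0/1.
#' @param window_index 0-based index of the window within its recording.
#' @param onset 0-based sample index of the window start in the recording.
#' @return An object of class `epoch_window`.
#' @export
epoch_window <- function(data, subject_id, recording_id, label,
                         window_index, onset) {
  structure(
    list(data = data, subject_id = as.character(subject_id),
         recording_id = as.character(recording_id), label = as.integer(label),
         window_index = as.integer(window_index), onset = as.integer(onset)),
    class = "epoch_window")
}

# Metadata of a list of windows as a data.frame (one row per window).
window_meta <- function(windows) {
  data.frame(
    subject_id = vapply(windows, `[[`, "", "subject_id"),
    recording_id = vapply(windows, `[[`, "", "recording_id"),
    label = vapply(windows, `[[`, 0L, "label"),
    window_index = vapply(windows, `[[`, 0L, "window_index"),
    stringsAsFactors = FALSE)
}
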