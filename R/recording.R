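#' Continuous multichannel LFP recording
#'
#' Thin container for a channels-by-samples matrix in microvolts, its
#' sampling rate, hemisphere-tagged channel labels and an embedded event
#' table (one row per stimulus/feedback event, onsets in seconds).
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one unique label per channel
#'   (e.g. `"dACC_left"`, `"dACC_right"`).
#' @param events `data.frame` with at least `onset_s`, `event`
#'   (`"stimulus"` or `"feedback"`) and `trial_index`; trial metadata
#'   columns (outcome, novelty, ...) ride along.
#' @return An object of class `lfp_recording`.
#' @export
new_recording <- function(data, fs, channel_labels, events = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (fs <= 0) stop("fs must be positive")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) stop("one label per channel required")
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  dur <- ncol(data) / fs
  if (!is.null(events)) {
    stopifnot(is.data.frame(events), all(c("onset_s", "event") %in% names(events)))
    if (any(events$onset_s < 0 | events$onset_s > dur))
      stop("event onsets must lie within the recording duration")
  }
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 events = events),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (!is.null(x$events))
    cat(sprintf("  events: %d (%s)\n", nrow(x$events),
                paste(unique(x$events$event), collapse = ", ")))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `lfp_recording`.
#' @return Length in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs
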