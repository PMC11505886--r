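#' Multichannel EEG recording
#'
#' Lightweight container for a channels x samples signal matrix with its
#' sampling rate, ordered channel labels, group tag and subject id. All
#' pipeline stages accept and return this class.
#'
#' @param signal Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of channel labels, one per row of
#'   `signal`.
#' @param group Group tag, e.g. `"HC"` or `"SZ"`.
#' @param subject_id Subject identifier string.
#'
#' @return An object of class `eeg_recording`: a list with elements
#'   `signal`, `fs`, `channels`, `group`, `subject_id`.
#' @export
eeg_recording <- function(signal, fs, channels = NULL, group = NA_character_,
                          subject_id = NA_character_) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal) || !all(is.finite(signal))) {
    stop("signal must be a finite numeric matrix")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar (Hz)")
  }
  if (is.null(channels)) {
    channels <- sprintf("ch%02d", seq_len(nrow(signal)))
  }
  if (length(channels) != nrow(signal)) {
    stop("length(channels) must equal nrow(signal)")
  }
  structure(
    list(signal = signal, fs = fs, channels = as.character(channels),
         group = group, subject_id = subject_id),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)",
    nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs
  ))
  if (!is.na(x$group)) cat(sprintf("  group=%s", x$group))
  if (!is.na(x$subject_id)) cat(sprintf("  subject=%s", x$subject_id))
  cat("\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$signal)

n_samples <- function(rec) ncol(rec$signal)
n_channels <- function(rec) nrow(rec$signal)

#' Write a recording to delimited text
#'
#' Serializes the signal matrix as CSV (channels in columns, one row per
#' sample) with a JSON sidecar holding sampling rate, channel labels, group
#' and subject id.
#'
#' @param rec An [eeg_recording()].
#' @param path Output CSV path; the sidecar is written to `<path>.json`.
#' @return Invisibly, the CSV path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  m <- t(rec$signal)
  colnames(m) <- rec$channels
  utils::write.csv(m, path, row.names = FALSE)
  meta <- list(fs = rec$fs, channels = rec$channels,
               group = rec$group, subject_id = rec$subject_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV path with accompanying `<path>.json` sidecar.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- utils::read.csv(path, check.names = FALSE)
  eeg_recording(t(as.matrix(m)), fs = meta$fs, channels = meta$channels,
                group = meta$group, subject_id = meta$subject_id)
}
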