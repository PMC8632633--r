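#' Construct an EEG recording
#'
#' A recording is a 19 x T matrix of samples in microvolts with the 10-20
#' channel labels as rownames, a sampling rate, and a reference tag.
#'
#' @param samples Numeric matrix, channels x time (microvolts). Rownames, if
#'   present, must be the 19 canonical 10-20 labels (any order; rows are
#'   reordered canonically).
#' @param fs Sampling rate in Hz.
#' @param reference `"as-recorded"` or `"common-average"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, reference = c("as-recorded", "common-average")) {
  reference <- match.arg(reference)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (channels x time)")
  }
  if (nrow(samples) != length(eeg_channels)) {
    stop("recording must have exactly ", length(eeg_channels), " channels, got ",
         nrow(samples))
  }
  if (is.null(rownames(samples))) {
    rownames(samples) <- eeg_channels
  } else {
    if (!setequal(rownames(samples), eeg_channels)) {
      bad <- setdiff(rownames(samples), eeg_channels)
      stop("unknown channel label(s): ", paste(bad, collapse = ", "))
    }
    samples <- samples[eeg_channels, , drop = FALSE]
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("`fs` must be a positive scalar")
  structure(
    list(samples = samples, fs = fs, reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> 19 channels x %d samples (%.1f s @ %g Hz), reference: %s\n",
    ncol(x$samples), ncol(x$samples) / x$fs, x$fs, x$reference
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$fs

#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean across the 19 channels from every
#' channel, making downstream spectra independent of the recording
#' reference montage. Idempotent; refuses an already re-referenced
#' recording unless `force = TRUE`.
#'
#' @param rec An `eeg_recording`.
#' @param force Re-reference even if already tagged `"common-average"`.
#' @return An `eeg_recording` tagged `"common-average"` whose channel mean
#'   is zero at every sample.
#' @export
rereference_common_average <- function(rec, force = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$reference == "common-average" && !force) {
    stop("recording is already common-average referenced; use force = TRUE to redo")
  }
  x <- rec$samples
  x <- sweep(x, 2, colMeans(x))
  eeg_recording(x, rec$fs, reference = "common-average")
}

#' Split a recording into its first and second temporal halves
#'
#' Used by split-half augmentation and split-half reliability screening.
#'
#' @param rec An `eeg_recording`.
#' @return List of two `eeg_recording`s (`first`, `second`), each half the
#'   duration (odd trailing sample dropped).
#' @export
split_halves <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$samples)
  h <- n %/% 2
  if (h < 1) stop("recording too short to split")
  list(
    first  = eeg_recording(rec$samples[, seq_len(h), drop = FALSE], rec$fs,
                           reference = rec$reference),
    second = eeg_recording(rec$samples[, (h + 1):(2 * h), drop = FALSE], rec$fs,
                           reference = rec$reference)
  )
}
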