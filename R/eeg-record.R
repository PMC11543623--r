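#' Construct an EEG record
#'
#' A multichannel EEG time series in microvolts with its sampling rate and
#' the lights-off/lights-on span. Samples are stored as a numeric matrix
#' (samples x channels); indices are 0-based and intervals half-open
#' throughout the package.
#'
#' @param samples Numeric matrix, one column per channel, in microvolts, with
#'   column names (e.g. `C3`, `C4`).
#' @param fs Sampling rate in Hz (> 0).
#' @param lights_off,lights_on 0-based sample indices bounding the scored
#'   span; defaults cover the whole record.
#' @param start_time Optional POSIXct recording start.
#' @return Object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs, lights_off = 0L,
                       lights_on = nrow(samples), start_time = NULL) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1,
                                               dimnames = list(NULL, "C3"))
  if (is.null(colnames(samples))) {
    abort("samples must have channel names as column names")
  }
  if (fs <= 0) abort("fs must be positive")
  if (!(lights_off < lights_on && lights_on <= nrow(samples))) {
    abort("need lights_off < lights_on <= record length")
  }
  structure(list(samples = samples, fs = fs,
                 lights_off = as.integer(lights_off),
                 lights_on = as.integer(lights_on),
                 start_time = start_time),
            class = "eeg_record")
}

#' @exportS3Method base::print
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d ch (%s), %.1f min @ %g Hz\n",
              ncol(x$samples), paste(colnames(x$samples), collapse = ", "),
              nrow(x$samples) / x$fs / 60, x$fs))
  invisible(x)
}

#' Channel names of an EEG record
#' @param record An [eeg_record()].
#' @return Character vector.
#' @export
channels <- function(record) colnames(record$samples)

#' Extract one channel as a numeric vector
#' @param record An [eeg_record()].
#' @param channel Channel name.
#' @return Numeric vector in microvolts.
#' @export
channel_signal <- function(record, channel) {
  if (!channel %in% channels(record)) {
    abort(sprintf("channel %s not present (have: %s)", channel,
                  paste(channels(record), collapse = ", ")))
  }
  record$samples[, channel]
}
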