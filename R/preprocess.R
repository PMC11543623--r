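#' High-pass filter an EEG record
#'
#' Removes DC and slow drift with a zero-phase (forward-backward) 4th-order
#' Butterworth high-pass at the given cutoff, normalising recordings across
#' acquisition settings. The default 0.5 Hz cutoff is the package-wide
#' convention; zero-phase realisation avoids the phase distortion that would
#' shift spindle peak times.
#'
#' @param record An [eeg_record()].
#' @param cutoff Cutoff frequency in Hz, default 0.5; must be below Nyquist.
#' @param order Butterworth order (applied forward and backward), default 4.
#' @return An [eeg_record()] of identical length.
#' @export
highpass <- function(record, cutoff = 0.5, order = 4) {
  if (cutoff >= record$fs / 2) abort("cutoff must be below Nyquist")
  if (record$fs <= 2 * cutoff) abort("fs must exceed 2 x cutoff")
  bf <- signal::butter(order, cutoff / (record$fs / 2), type = "high")
  record$samples <- apply(record$samples, 2, function(x) {
    signal::filtfilt(bf, x)
  })
  record
}

# zero-phase Butterworth low-pass, used by the spindle/SO paths
lowpass <- function(record, cutoff, order = 4) {
  if (cutoff >= record$fs / 2) abort("cutoff must be below Nyquist")
  bf <- signal::butter(order, cutoff / (record$fs / 2), type = "low")
  record$samples <- apply(record$samples, 2, function(x) {
    signal::filtfilt(bf, x)
  })
  record
}

#' Flag artifact segments by RMS amplitude
#'
#' Computes the root-mean-squared amplitude of each contiguous 3-second
#' segment (grid anchored at lights-off) per channel and flags segments with
#' RMS at or below `lo` (flat/disconnected) or at or above `hi` (movement or
#' sweat artifact). The 1 and 250 microvolt defaults bracket the
#' physiological 10-100 microvolt range conservatively.
#'
#' @param record An [eeg_record()].
#' @param seg_len Segment length in seconds, default 3.
#' @param lo,hi RMS thresholds in microvolts; a segment is flagged iff
#'   `rms <= lo` or `rms >= hi`.
#' @return Tibble of class `artifact_mask`: one row per segment x channel
#'   with columns `segment` (0-based), `channel`, `rms`, `flagged`.
#' @export
reject_artifacts_rms <- function(record, seg_len = 3, lo = 1, hi = 250) {
  if (seg_len <= 0) abort("seg_len must be positive")
  spseg <- round(seg_len * record$fs)
  span <- record$lights_on - record$lights_off
  n_seg <- span %/% spseg
  if (n_seg < 1) abort("record shorter than one segment")
  out <- purrr::map_dfr(channels(record), function(ch) {
    x <- channel_signal(record, ch)[(record$lights_off + 1):record$lights_on]
    x <- x[seq_len(n_seg * spseg)]
    m <- matrix(x, nrow = spseg)
    rms <- sqrt(colMeans(m^2))
    tibble(segment = seq_len(n_seg) - 1L, channel = ch, rms = rms,
           flagged = rms <= lo | rms >= hi)
  })
  class(out) <- c("artifact_mask", class(out))
  attr(out, "seg_len") <- seg_len
  out
}

#' Map hypnogram epochs to sample ranges and 3-second segments
#'
#' Aligns each scored 30-second epoch to its half-open sample range
#' `[lights_off + 30k*fs, lights_off + 30(k+1)*fs)` and to the ten 3-second
#' segments tiling it. A partial trailing epoch in the recording is left
#' unassigned.
#'
#' @param record An [eeg_record()].
#' @param hypnogram A [hypnogram()]; must fit within the record span from
#'   lights-off.
#' @return Tibble, one row per epoch, with columns `epoch`, `stage`,
#'   `start_sample`, `end_sample` (half-open, 0-based) and `segments` (list
#'   column of 0-based segment indices on the lights-off-anchored 3-s grid).
#' @export
align_epochs <- function(record, hypnogram) {
  spe <- EPOCH_SEC * record$fs
  span <- record$lights_on - record$lights_off
  if (n_epochs(hypnogram) * spe > span) {
    abort("hypnogram longer than the recording span from lights_off")
  }
  segs_per_epoch <- EPOCH_SEC %/% SEGMENT_SEC
  tibble(
    epoch = hypnogram$epoch,
    stage = hypnogram$stage,
    start_sample = as.integer(record$lights_off + hypnogram$epoch * spe),
    end_sample = as.integer(record$lights_off + (hypnogram$epoch + 1) * spe),
    segments = purrr::map(hypnogram$epoch, function(k) {
      as.integer(k * segs_per_epoch + seq_len(segs_per_epoch) - 1L)
    })
  )
}
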