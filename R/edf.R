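#' Write an EEG record to EDF
#'
#' Writes a continuous European Data Format file (EDF: fixed 256-byte header,
#' one 256-byte signal header per channel, then 1-second data records of
#' little-endian 16-bit integers). Physical scaling is chosen per channel
#' from the signal range. The record is padded with zeros to a whole number
#' of 1-second data records; `read_edf()` returns the padded length.
#'
#' @param record An [eeg_record()] with an integer sampling rate.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  fs <- record$fs
  if (fs != round(fs)) abort("EDF writer requires an integer sampling rate")
  x <- record$samples
  ns <- ncol(x)
  n_rec <- ceiling(nrow(x) / fs)
  if (nrow(x) < n_rec * fs) {
    x <- rbind(x, matrix(0, n_rec * fs - nrow(x), ns,
                         dimnames = list(NULL, colnames(x))))
  }
  pmin_ <- apply(x, 2, min); pmax_ <- apply(x, 2, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  pad <- function(s, w) formatC(as.character(s), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (1 + ns), 8), pad("", 44), pad(n_rec, 8), pad(1, 8), pad(ns, 4)
  ), con, eos = NULL)
  field <- function(vals, w) writeChar(paste(vapply(vals, pad, "", w = w),
                                             collapse = ""), con, eos = NULL)
  field(colnames(x), 16)                      # label
  field(rep("", ns), 80)                      # transducer
  field(rep("uV", ns), 8)                     # physical dimension
  field(sprintf("%.6g", pmin_), 8)
  field(sprintf("%.6g", pmax_), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("HP:0.5Hz", ns), 80)              # prefiltering
  field(rep(fs, ns), 8)                       # samples per data record
  field(rep("", ns), 32)                      # reserved

  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((x[idx, ch] - pmin_[ch]) / gain[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @param lights_off,lights_on Optional 0-based sample indices to attach to
#'   the returned record (EDF itself carries no lights markers).
#' @return `read_edf()` returns an [eeg_record()].
#' @export
read_edf <- function(path, lights_off = NULL, lights_on = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  n_rec <- as.integer(substr(hdr, 237, 244))
  dur <- as.numeric(substr(hdr, 245, 252))
  ns <- as.integer(substr(hdr, 253, 256))
  sig <- readChar(con, 256 * ns, useBytes = TRUE)
  fld <- function(off, w) {
    vapply(seq_len(ns), function(i) {
      trimws(substr(sig, off + (i - 1) * w + 1, off + i * w))
    }, "")
  }
  labels <- fld(0, 16)
  pmin_ <- as.numeric(fld(ns * (16 + 80 + 8), 8))
  pmax_ <- as.numeric(fld(ns * (16 + 80 + 8 + 8), 8))
  dmin <- as.numeric(fld(ns * (16 + 80 + 8 + 8 + 8), 8))
  dmax <- as.numeric(fld(ns * (16 + 80 + 8 + 8 + 8 + 8), 8))
  spr <- as.integer(fld(ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80), 8))
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  out <- matrix(0, n_rec * spr[1], ns, dimnames = list(NULL, labels))
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      out[((r - 1) * spr[ch] + 1):(r * spr[ch]), ch] <-
        (dig - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  eeg_record(out, fs = spr[1] / dur,
             lights_off = lights_off %||% 0L,
             lights_on = lights_on %||% nrow(out))
}
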