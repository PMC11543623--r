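#' Construct a hypnogram
#'
#' A hypnogram is the per-epoch sequence of scored sleep stages between
#' lights-off and lights-on, one label per 30-second epoch. It is stored as a
#' tibble with columns `epoch` (0-based index) and `stage` (factor over
#' [sleep_stages()]), carrying the epoch length as an attribute.
#'
#' @param stages Character or factor vector of stage labels (W/N1/N2/N3/REM),
#'   one per 30-s epoch, in temporal order.
#' @return A tibble of class `hypnogram`.
#' @export
#' @examples
#' h <- hypnogram(c("W", "W", "N1", "N2", "N2"))
#' n_epochs(h)
hypnogram <- function(stages) {
  stages <- as.character(stages)
  assert_stages(stages)
  out <- tibble(
    epoch = seq_along(stages) - 1L,
    stage = factor(stages, levels = sleep_stages())
  )
  class(out) <- c("hypnogram", class(out))
  attr(out, "epoch_sec") <- EPOCH_SEC
  out
}

#' @exportS3Method base::print
print.hypnogram <- function(x, ...) {
  tab <- table(x$stage)
  cat(sprintf("<hypnogram> %d epochs (%.1f min): %s\n",
              nrow(x), nrow(x) * EPOCH_SEC / 60,
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Number of scored epochs
#' @param h A [hypnogram()].
#' @return Integer epoch count.
#' @export
n_epochs <- function(h) nrow(h)

#' Read and write hypnograms as tab-separated text
#'
#' One row per 30-s epoch with columns `epoch`, `stage`, `lights_off_flag`
#' (1 within the lights-off to lights-on span; this dialect scores only that
#' span, so the flag is 1 throughout).
#'
#' @param h A [hypnogram()].
#' @param path File path.
#' @return `write_hypnogram()` returns `path` invisibly; `read_hypnogram()`
#'   returns a [hypnogram()].
#' @export
write_hypnogram <- function(h, path) {
  df <- data.frame(epoch = h$epoch, stage = as.character(h$stage),
                   lights_off_flag = 1L)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  hypnogram(df$stage[order(df$epoch)])
}
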