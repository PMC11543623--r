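#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` for time-bandwidth
#' product `nw`, as eigenvectors of the symmetric tridiagonal Slepian matrix.
#' Tapers are unit-energy; used by [multitaper_psd()].
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product, default 2.
#' @param k Number of tapers, default `2 * nw - 1`.
#' @return n x k matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 2, k = 2 * nw - 1) {
  if (k >= n) abort("need fewer tapers than samples")
  w <- nw / n
  t_ <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t_) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  # polarity convention: positive mean for symmetric tapers, positive
  # initial slope for antisymmetric ones
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) V[, j] <- -V[, j]
    } else if (V[2, j] - V[1, j] < 0) V[, j] <- -V[, j]
  }
  sweep(V, 2, sqrt(colSums(V^2)), "/")
}

# averaged-eigenspectrum multitaper PSD (one-sided, density in uV^2/Hz)
multitaper_psd <- function(x, fs, nw = 2, k = 2 * nw - 1) {
  n <- length(x)
  tapers <- dpss_tapers(n, nw, k)
  nf <- n %/% 2 + 1
  S <- rowSums(vapply(seq_len(k), function(j) {
    Mod(fft(x * tapers[, j])[seq_len(nf)])^2 / fs
  }, numeric(nf))) / k
  # fold negative frequencies into the one-sided density
  if (n %% 2 == 0) S[2:(nf - 1)] <- 2 * S[2:(nf - 1)] else
    S[2:nf] <- 2 * S[2:nf]
  list(freq = (seq_len(nf) - 1) * fs / n, psd = S)
}

# integrate a one-sided PSD over [lo, hi) in Hz
band_power_from_psd <- function(psd, lo, hi) {
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= lo - 1e-9 & psd$freq < hi - 1e-9
  sum(psd$psd[sel]) * df
}

#' Multitaper band powers over sliding windows
#'
#' Estimates absolute power in the four canonical bands (delta 0.5-4, theta
#' 4-8, alpha 8-12, beta 12-30 Hz) with multitaper spectral density
#' estimation on 2-second windows with 1-second overlap, the standard
#' short-window tapering scheme for stage-resolved PSG spectra.
#'
#' @param x Numeric signal in microvolts.
#' @param fs Sampling rate in Hz (>= 64).
#' @param win Window length in seconds, default 2.
#' @param overlap Overlap in seconds, default 1.
#' @param nw Time-bandwidth product, default 2.
#' @param k Tapers, default 3.
#' @return Tibble, one row per window: `start_s`, `delta`, `theta`, `alpha`,
#'   `beta` (absolute power, microvolt^2). Empty (with a warning) if the
#'   signal is shorter than one window.
#' @export
multitaper_bandpowers <- function(x, fs, win = 2, overlap = 1, nw = 2, k = 3) {
  if (fs < 64) abort("fs must be >= 64 Hz")
  nwin <- round(win * fs)
  hop <- round((win - overlap) * fs)
  if (length(x) < nwin) {
    warn("signal shorter than one window; returning no band powers")
    return(tibble(start_s = numeric(), delta = numeric(), theta = numeric(),
                  alpha = numeric(), beta = numeric()))
  }
  starts <- seq(1, length(x) - nwin + 1, by = hop)
  tapers <- dpss_tapers(nwin, nw, k)
  nf <- nwin %/% 2 + 1
  freq <- (seq_len(nf) - 1) * fs / nwin
  df <- fs / nwin
  edges <- band_edges()
  sel <- lapply(edges, function(e) freq >= e[1] - 1e-9 & freq < e[2] - 1e-9)
  pw <- vapply(starts, function(i) {
    seg <- x[i:(i + nwin - 1)]
    S <- rowSums(vapply(seq_len(k), function(j) {
      Mod(fft(seg * tapers[, j])[seq_len(nf)])^2 / fs
    }, numeric(nf))) / k
    if (nwin %% 2 == 0) S[2:(nf - 1)] <- 2 * S[2:(nf - 1)] else
      S[2:nf] <- 2 * S[2:nf]
    vapply(sel, function(s) sum(S[s]) * df, 0)
  }, numeric(4))
  tibble(start_s = (starts - 1) / fs,
         delta = pw[1, ], theta = pw[2, ], alpha = pw[3, ], beta = pw[4, ])
}

#' Relative band powers of one window
#'
#' Divides each band's absolute power by the total over the four bands.
#'
#' @param powers Numeric vector or one-row tibble with `delta`, `theta`,
#'   `alpha`, `beta`.
#' @return Named numeric vector of four fractions summing to 1. Zero total
#'   power is an error (window should be excluded upstream).
#' @export
relative_power <- function(powers) {
  if (is.data.frame(powers)) {
    powers <- unlist(powers[1, c("delta", "theta", "alpha", "beta")])
  }
  tot <- sum(powers)
  if (!is.finite(tot) || tot <= 0) {
    abort("zero or invalid total power: window must be excluded")
  }
  setNames(as.numeric(powers) / tot, c("delta", "theta", "alpha", "beta"))
}

#' Average window band powers to 30-second epochs
#'
#' Windows overlapping any flagged 3-second segment of the given channel are
#' discarded; surviving absolute powers are averaged per epoch. Epochs with
#' no surviving window are marked missing (`NA`).
#'
#' @param windows Output of [multitaper_bandpowers()] for one channel; window
#'   start times are relative to lights-off.
#' @param epoch_map Output of [align_epochs()].
#' @param mask Optional [reject_artifacts_rms()] mask (rows for the same
#'   channel).
#' @param win Window length in seconds (for overlap computation), default 2.
#' @return Tibble, one row per epoch: `epoch`, `stage`, `n_windows`,
#'   `delta`, `theta`, `alpha`, `beta` (mean absolute power).
#' @export
aggregate_to_epochs <- function(windows, epoch_map, mask = NULL, win = 2) {
  flagged <- if (is.null(mask)) integer(0) else mask$segment[mask$flagged]
  w <- windows
  # 0-based 3-s segments overlapped by each half-open window [start, start+win)
  seg_first <- floor(w$start_s / SEGMENT_SEC)
  seg_last <- ceiling((w$start_s + win) / SEGMENT_SEC) - 1
  w$keep <- purrr::map2_lgl(seg_first, seg_last,
                            function(a, b) !any(seq(a, b) %in% flagged))
  w$epoch <- floor(w$start_s / EPOCH_SEC)
  # windows straddling an epoch boundary belong to the epoch they start in
  out <- purrr::map_dfr(seq_len(nrow(epoch_map)), function(i) {
    ep <- epoch_map$epoch[i]
    ww <- w[w$epoch == ep & w$keep & w$start_s + win <= (ep + 1) * EPOCH_SEC, ]
    if (nrow(ww) == 0) {
      tibble(epoch = ep, stage = epoch_map$stage[i], n_windows = 0L,
             delta = NA_real_, theta = NA_real_, alpha = NA_real_,
             beta = NA_real_)
    } else {
      tibble(epoch = ep, stage = epoch_map$stage[i], n_windows = nrow(ww),
             delta = mean(ww$delta), theta = mean(ww$theta),
             alpha = mean(ww$alpha), beta = mean(ww$beta))
    }
  })
  out
}

#' Per-stage log relative band powers
#'
#' Computes relative power within each surviving 30-second epoch, averages
#' the fractions across the epochs of each stage, and natural-log transforms
#' the stage means. Stages absent from the hypnogram (or with no surviving
#' epochs) are reported missing, not zero.
#'
#' @param epoch_powers Output of [aggregate_to_epochs()].
#' @return Tibble, one row per stage x band: `stage`, `band`,
#'   `rel_power` (stage-mean fraction), `log_rel_power`, `n_epochs`.
#' @export
stage_features <- function(epoch_powers) {
  ep <- filter(epoch_powers, .data$n_windows > 0)
  tot <- ep$delta + ep$theta + ep$alpha + ep$beta
  rel <- mutate(ep, delta = .data$delta / tot, theta = .data$theta / tot,
                alpha = .data$alpha / tot, beta = .data$beta / tot)
  long <- tidyr::pivot_longer(rel, c("delta", "theta", "alpha", "beta"),
                              names_to = "band", values_to = "rel")
  means <- summarise(group_by(long, .data$stage, .data$band),
                     rel_power = mean(.data$rel), n_epochs = dplyr::n_distinct(.data$epoch),
                     .groups = "drop")
  full <- tidyr::expand_grid(stage = factor(sleep_stages(), sleep_stages()),
                             band = c("delta", "theta", "alpha", "beta"))
  out <- left_join(full, means, by = c("stage", "band"))
  mutate(out,
         n_epochs = tidyr::replace_na(.data$n_epochs, 0L),
         log_rel_power = log(.data$rel_power))
}

#' End-to-end spectral features for one recording
#'
#' Runs the spectral pipeline per channel (band powers on 2-s windows,
#' artifact-aware aggregation to epochs, per-stage relative power), then
#' averages the per-channel stage means across channels before the log
#' transform.
#'
#' @param record A high-pass-filtered [eeg_record()].
#' @param hypnogram A [hypnogram()].
#' @param channels_used Channels to analyse, default C3/C4 intersected with
#'   what the record has.
#' @param mask Optional artifact mask; computed with defaults when `NULL`.
#' @param ... Passed to [multitaper_bandpowers()].
#' @return Tibble, one row per stage x band: `channel_set`, `stage`, `band`,
#'   `rel_power`, `log_rel_power`, `n_epochs`.
#' @export
spectral_features <- function(record, hypnogram,
                              channels_used = intersect(c("C3", "C4"),
                                                        channels(record)),
                              mask = NULL, ...) {
  if (length(channels_used) == 0) abort("no usable channels")
  if (is.null(mask)) mask <- reject_artifacts_rms(record)
  emap <- align_epochs(record, hypnogram)
  per_ch <- purrr::map_dfr(channels_used, function(ch) {
    x <- channel_signal(record, ch)[(record$lights_off + 1):record$lights_on]
    wins <- multitaper_bandpowers(x, record$fs, ...)
    ep <- aggregate_to_epochs(wins, emap, filter(mask, .data$channel == ch))
    mutate(stage_features(ep), channel = ch)
  })
  out <- summarise(group_by(per_ch, .data$stage, .data$band),
                   rel_power = mean(.data$rel_power),
                   n_epochs = max(.data$n_epochs),
                   .groups = "drop")
  mutate(out, log_rel_power = log(.data$rel_power),
         channel_set = paste(channels_used, collapse = "+"), .before = 1)
}
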