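#' Prepare one channel for spindle analysis
#'
#' Resamples the (already 0.5 Hz high-pass-filtered) signal to 128 Hz,
#' low-pass filters at 35 Hz, and rejects N2 epochs whose delta-band power
#' exceeds 2.5 times the mean delta power in a 15-epoch sliding window
#' (window shrinking symmetrically at the edges when fewer epochs are
#' available).
#'
#' @param record An [eeg_record()], high-pass filtered upstream.
#' @param hypnogram A [hypnogram()].
#' @param channel Channel to analyse, default `"C3"`.
#' @param target_fs Resampling rate, fixed default 128 Hz.
#' @return List of class `spindle_signal`: `x` (numeric signal), `fs`,
#'   `hypnogram`, `channel`, `n2_kept` (0-based indices of retained N2
#'   epochs), `n2_rejected` (indices rejected by the delta-power rule).
#' @export
prepare_spindle_signal <- function(record, hypnogram, channel = "C3",
                                   target_fs = 128) {
  x <- channel_signal(record, channel)[(record$lights_off + 1):record$lights_on]
  fs <- record$fs
  if (fs != target_fs) {
    frac <- gcd_frac(target_fs, fs)
    x <- signal::resample(x, frac[1], frac[2])
    fs <- target_fs
  }
  bf <- signal::butter(4, 35 / (fs / 2), type = "low")
  x <- signal::filtfilt(bf, x)

  spe <- EPOCH_SEC * fs
  n_ep <- min(n_epochs(hypnogram), length(x) %/% spe)
  bd <- signal::butter(4, c(0.5, 4) / (fs / 2), type = "pass")
  xd <- signal::filtfilt(bd, x)
  delta_pw <- vapply(seq_len(n_ep), function(k) {
    mean(xd[((k - 1) * spe + 1):(k * spe)]^2)
  }, 0)

  n2 <- which(as.character(hypnogram$stage[seq_len(n_ep)]) == "N2") - 1L
  rejected <- integer(0)
  if (length(n2) > 0) {
    # sliding mean over the N2 epoch sequence, half-width 7 (15-epoch window)
    pw <- delta_pw[n2 + 1L]
    hw <- 7L
    loc_mean <- vapply(seq_along(pw), function(i) {
      lo <- max(1L, i - hw); hi <- min(length(pw), i + hw)
      mean(pw[lo:hi])
    }, 0)
    rejected <- n2[pw > 2.5 * loc_mean]
  }
  structure(list(x = x, fs = fs, hypnogram = hypnogram, channel = channel,
                 n2_kept = setdiff(n2, rejected), n2_rejected = rejected),
            class = "spindle_signal")
}

# smallest integer ratio p/q equal to a/b
gcd_frac <- function(a, b) {
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  a <- round(a * 1000); b <- round(b * 1000)
  d <- g(a, b)
  c(a / d, b / d)
}

# smoothed complex-Morlet wavelet power (squared magnitude, 0.1-s moving
# average) -- the thresholded quantity of the spindle detector
morlet_power <- function(x, fs, f0 = 13.5, n_cycles = 7, smooth_s = 0.1) {
  sigma <- n_cycles / (2 * pi * f0)
  half <- ceiling(3.5 * sigma * fs)
  tt <- (-half:half) / fs
  kern <- exp(2i * pi * f0 * tt) * exp(-tt^2 / (2 * sigma^2))
  kern <- kern / sum(Mod(kern))
  n <- length(x); m <- length(kern)
  nf <- stats::nextn(n + m - 1, 2)
  conv <- fft(fft(c(x, rep(0, nf - n))) * fft(c(kern, rep(0, nf - m))),
              inverse = TRUE) / nf
  pw <- Mod(conv[(half + 1):(half + n)])^2
  w <- max(1L, round(smooth_s * fs))
  sm <- as.numeric(stats::filter(pw, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- pw[is.na(sm)]
  sm
}

#' Detect sleep spindles in N2
#'
#' Morlet-wavelet thresholding: the signal is convolved with a complex
#' Morlet wavelet centred at 13.5 Hz, the squared magnitude (wavelet power)
#' smoothed over 0.1 s, and events detected within retained N2 epochs where
#' the smoothed power exceeds 4.5 times its all-N2 mean for at least 0.3 s
#' (core), extended up to 0.5 s on each side while it stays above twice
#' that mean (flank).
#' Events closer than 0.5 s are merged; events longer than 3 s are rejected.
#' Each spindle's observed frequency is the dominant 11-15 Hz component of
#' the raw (35 Hz low-passed) signal over its span, classing it fast
#' (13-15 Hz) or slow (11-<13 Hz).
#'
#' @param prep A `spindle_signal` from [prepare_spindle_signal()].
#' @param f0 Wavelet centre frequency, default 13.5 Hz.
#' @param n_cycles Morlet cycles, default 7.
#' @param core_mult,flank_mult Threshold multipliers (defaults 4.5 and 2).
#' @param core_min_s Minimum core duration, default 0.3 s.
#' @param merge_gap_s Merge gap, default 0.5 s.
#' @param max_dur_s Maximum duration, default 3 s.
#' @return Tibble of spindle events: `channel`, `start_s`, `end_s`,
#'   `peak_s`, `freq`, `class` (`"fast"`/`"slow"`); empty (with a warning)
#'   when no N2 is available.
#' @export
detect_spindles <- function(prep, f0 = 13.5, n_cycles = 7, core_mult = 4.5,
                            flank_mult = 2, core_min_s = 0.3,
                            merge_gap_s = 0.5, max_dur_s = 3) {
  empty <- tibble(channel = character(), start_s = numeric(),
                  end_s = numeric(), peak_s = numeric(), freq = numeric(),
                  class = character())
  if (length(prep$n2_kept) == 0) {
    warn("no N2 epochs available: no spindles detected")
    return(empty)
  }
  fs <- prep$fs
  spe <- EPOCH_SEC * fs
  mag <- morlet_power(prep$x, fs, f0, n_cycles)
  n2_samp <- unlist(lapply(prep$n2_kept, function(k) (k * spe + 1):((k + 1) * spe)))
  n2_samp <- n2_samp[n2_samp <= length(mag)]
  mu <- mean(mag[n2_samp])

  in_n2 <- rep(FALSE, length(mag))
  in_n2[n2_samp] <- TRUE
  core <- mag > core_mult * mu & in_n2
  r <- rle(core)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= core_min_s * fs
  if (!any(keep)) return(empty)
  ev <- tibble(s = starts[keep], e = ends[keep])
  # flank extension: up to 0.5 s per side while magnitude stays >= 2x mean
  max_ext <- round(0.5 * fs)
  thr2 <- flank_mult * mu
  ev$s <- vapply(ev$s, function(s) {
    lo <- max(1, s - max_ext)
    while (s > lo && mag[s - 1] >= thr2 && in_n2[s - 1]) s <- s - 1
    s
  }, 0)
  ev$e <- vapply(ev$e, function(e) {
    hi <- min(length(mag), e + max_ext)
    while (e < hi && mag[e + 1] >= thr2 && in_n2[e + 1]) e <- e + 1
    e
  }, 0)
  # merge events separated by less than the merge gap
  ev <- arrange(ev, .data$s)
  merged <- list(ev[1, ])
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      last <- merged[[length(merged)]]
      if (ev$s[i] - last$e <= merge_gap_s * fs) {
        merged[[length(merged)]]$e <- max(last$e, ev$e[i])
      } else merged[[length(merged) + 1]] <- ev[i, ]
    }
  }
  ev <- bind_rows(merged)
  ev <- filter(ev, (.data$e - .data$s + 1) / fs <= max_dur_s)
  if (nrow(ev) == 0) return(empty)

  purrr::pmap_dfr(ev, function(s, e) {
    pk <- s - 1 + which.max(mag[s:e])
    seg <- prep$x[s:e]
    freq <- dominant_freq(seg, fs, lo = 11, hi = 15)
    tibble(channel = prep$channel, start_s = (s - 1) / fs, end_s = e / fs,
           peak_s = (pk - 1) / fs, freq = freq,
           class = ifelse(freq >= 13, "fast", "slow"))
  })
}

# dominant frequency of a short segment within [lo, hi] Hz (zero-padded
# periodogram with parabolic peak interpolation)
dominant_freq <- function(seg, fs, lo, hi) {
  n <- max(length(seg), 4 * fs)
  X <- Mod(fft(c(seg - mean(seg), rep(0, n - length(seg)))))^2
  f <- (seq_along(X) - 1) * fs / n
  sel <- which(f >= lo & f <= hi)
  i <- sel[which.max(X[sel])]
  if (i > 1 && i < length(X) - 1) {
    a <- X[i - 1]; b <- X[i]; cc <- X[i + 1]
    d <- 0.5 * (a - cc) / (a - 2 * b + cc)
    if (is.finite(d) && abs(d) < 1) return(f[i] + d * fs / n)
  }
  f[i]
}

#' Detect slow oscillations by zero-crossing timing
#'
#' Low-pass filters the whole signal at 4.5 Hz and, within N2 epochs, marks
#' every pair of consecutive positive-to-negative zero-crossings separated by
#' 0.8 to 2 seconds as one slow oscillation. Consecutive-crossing delimiting
#' guarantees non-overlapping events.
#'
#' @param prep A `spindle_signal` from [prepare_spindle_signal()] (signal
#'   must be high-pass filtered at 0.5 Hz upstream).
#' @param min_s,max_s Crossing-interval bounds, defaults 0.8 and 2 s.
#' @return Tibble of events: `channel`, `start_s`, `end_s`.
#' @export
detect_slow_oscillations <- function(prep, min_s = 0.8, max_s = 2) {
  fs <- prep$fs
  bf <- signal::butter(4, 4.5 / (fs / 2), type = "low")
  y <- signal::filtfilt(bf, prep$x)
  pn <- which(y[-length(y)] > 0 & y[-1] <= 0)
  if (length(pn) < 2) {
    return(tibble(channel = character(), start_s = numeric(),
                  end_s = numeric()))
  }
  spe <- EPOCH_SEC * fs
  n2 <- rep(FALSE, length(y))
  for (k in prep$n2_kept) {
    idx <- (k * spe + 1):min((k + 1) * spe, length(y))
    n2[idx] <- TRUE
  }
  s <- pn[-length(pn)]; e <- pn[-1]
  len <- (e - s) / fs
  ok <- len >= min_s & len <= max_s & n2[s] & n2[e]
  tibble(channel = prep$channel, start_s = (s[ok] - 1) / fs,
         end_s = (e[ok] - 1) / fs)
}

#' Couple spindles to slow oscillations and compute SO phase
#'
#' For each spindle whose peak lies within a slow oscillation (between its
#' delimiting positive-to-negative zero-crossings), the phase is the peak's
#' position as an angle: `360 * (peak - start) / (end - start)` degrees.
#' Uncoupled spindles get `NA` phase.
#'
#' @param spindles Tibble from [detect_spindles()].
#' @param sos Tibble from [detect_slow_oscillations()] (same channel and
#'   time axis).
#' @return `spindles` with added columns `so_id` (row index into `sos` or
#'   `NA`) and `phase_deg` in \[0, 360).
#' @export
couple_and_phase <- function(spindles, sos) {
  if (nrow(sos) > 1) {
    o <- order(sos$start_s)
    stopifnot(all(sos$end_s[o][-nrow(sos)] <= sos$start_s[o][-1] + 1e-9))
  }
  so_id <- rep(NA_integer_, nrow(spindles))
  phase <- rep(NA_real_, nrow(spindles))
  for (i in seq_len(nrow(spindles))) {
    hit <- which(sos$start_s <= spindles$peak_s[i] &
                   spindles$peak_s[i] <= sos$end_s)
    if (length(hit) > 0) {
      j <- hit[1]
      so_id[i] <- j
      phase[i] <- 360 * (spindles$peak_s[i] - sos$start_s[j]) /
        (sos$end_s[j] - sos$start_s[j])
    }
  }
  mutate(spindles, so_id = so_id, phase_deg = phase %% 360)
}

#' Per-channel spindle feature set
#'
#' Density (spindles per minute of N2), dispersion (variance of per-epoch
#' spindle counts divided by their mean; population variance by default),
#' and the circular mean SO phase at spindle peak for fast and slow
#' spindles.
#'
#' @param spindles Tibble from [couple_and_phase()] (phase column optional).
#' @param n2_epochs 0-based indices of retained N2 epochs.
#' @param variance `"population"` (default) or `"sample"` for the dispersion
#'   numerator.
#' @return One-row tibble: `channel`, `density`, `dispersion`,
#'   `phase_fast_deg`, `phase_slow_deg`, `n_spindles`, `n2_minutes`.
#' @export
spindle_features <- function(spindles, n2_epochs,
                             variance = c("population", "sample")) {
  variance <- match.arg(variance)
  if (length(n2_epochs) < 1) abort("need at least one N2 epoch")
  n2_min <- length(n2_epochs) * EPOCH_SEC / 60
  ch <- if (nrow(spindles) > 0) spindles$channel[1] else NA_character_
  counts <- vapply(n2_epochs, function(k) {
    sum(spindles$start_s >= k * EPOCH_SEC & spindles$start_s < (k + 1) * EPOCH_SEC)
  }, 0)
  m <- mean(counts)
  v <- if (variance == "population") mean((counts - m)^2) else var(counts)
  disp <- if (nrow(spindles) == 0 || m == 0) NA_real_ else v / m
  ph <- function(cls) {
    if (!"phase_deg" %in% names(spindles)) return(NA_real_)
    circular_mean_deg(stats::na.omit(
      spindles$phase_deg[spindles$class == cls]))
  }
  tibble(channel = ch, density = nrow(spindles) / n2_min,
         dispersion = disp, phase_fast_deg = ph("fast"),
         phase_slow_deg = ph("slow"), n_spindles = nrow(spindles),
         n2_minutes = n2_min)
}
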