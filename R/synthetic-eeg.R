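#' Default stage spectral profiles
#'
#' Target relative band powers (delta/theta/alpha/beta fractions summing to
#' 1), RMS amplitude, and N2/N3 event rates for each sleep stage, used by the
#' signal-tier generator. The fractions follow the canonical ordering of
#' stage spectra (alpha-dominant wake, progressively delta-dominant NREM);
#' amplitudes sit inside the physiological 10-100 microvolt range so clean
#' synthetic signal survives RMS artifact rejection.
#'
#' @return Tibble with columns `stage`, `f_delta`, `f_theta`, `f_alpha`,
#'   `f_beta`, `amplitude_rms`, `spindle_rate` (events/min, N2 only),
#'   `so_rate` (events/min, N2/N3).
#' @export
stage_profiles_default <- function() {
  tibble::tribble(
    ~stage, ~f_delta, ~f_theta, ~f_alpha, ~f_beta, ~amplitude_rms, ~spindle_rate, ~so_rate,
    "W",      0.30,     0.15,     0.35,    0.20,        30,             0,            0,
    "N1",     0.45,     0.30,     0.15,    0.10,        40,             0,            0,
    "N2",     0.60,     0.24,     0.11,    0.05,        50,             2,            3,
    "N3",     0.82,     0.11,     0.04,    0.03,        70,             0,            5,
    "REM",    0.45,     0.30,     0.12,    0.13,        35,             0,            0
  )
}

validate_stage_profiles <- function(profiles) {
  fr <- as.matrix(profiles[, c("f_delta", "f_theta", "f_alpha", "f_beta")])
  if (any(fr <= 0) || any(fr >= 1)) {
    abort("band fractions must lie strictly in (0, 1)")
  }
  if (any(abs(rowSums(fr) - 1) > 1e-9)) {
    abort("band fractions must sum to 1 within 1e-9")
  }
  if (any(profiles$amplitude_rms <= 1 | profiles$amplitude_rms >= 250)) {
    abort("amplitude_rms must lie in (1, 250) microvolts")
  }
  invisible(profiles)
}

# canonical band edges in Hz
band_edges <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30))
}

# band-limited Gaussian noise of exact target standard deviation
band_noise <- function(n, fs, lo, hi, target_sd) {
  pad <- round(2 * fs)
  w <- c(lo, hi) / (fs / 2)
  bf <- signal::butter(4, w, type = "pass")
  y <- signal::filtfilt(bf, rnorm(n + 2 * pad))
  y <- y[(pad + 1):(pad + n)]
  y * target_sd / stats::sd(y)
}

#' Synthesize multichannel EEG from a hypnogram
#'
#' Generates per-stage EEG as a sum of band-limited filtered Gaussian noise
#' components scaled so each band's variance fraction matches the stage
#' profile and total RMS matches the profile amplitude. N2 epochs receive
#' Hann-windowed spindle bursts at the configured frequency (Poisson counts
#' at the profile's `spindle_rate`); N2/N3 epochs receive slow-oscillation
#' sine cycles at 0.8-1.2 Hz. Optional artifact segments (flat or
#' high-amplitude) are inserted at known positions. Injected event times are
#' recorded as ground truth in `attr(record, "events")`.
#'
#' @param hypnogram A [hypnogram()]; every stage present must have a profile
#'   row.
#' @param profiles Stage profile tibble (see [stage_profiles_default()]).
#' @param fs Sampling rate in Hz (>= 100).
#' @param channels Channel names to generate (independent noise per channel;
#'   events are injected into every channel at the same times).
#' @param spindle_freq Spindle carrier frequency in Hz (default 13.5).
#' @param spindle_amp Spindle peak amplitude in microvolts.
#' @param spindle_dur Spindle duration in seconds.
#' @param so_amp Slow-oscillation amplitude in microvolts.
#' @param artifact_spec Optional tibble with columns `start_s`, `duration_s`,
#'   `type` (`"flat"` or `"high"`) describing segments to corrupt; total
#'   artifact duration must be < the record duration.
#' @param seed Integer seed.
#' @return An [eeg_record()] spanning the hypnogram, lights-off at sample 0.
#' @export
synthesize_eeg <- function(hypnogram, profiles = stage_profiles_default(),
                           fs = 128, channels = c("C3", "C4"),
                           spindle_freq = 13.5, spindle_amp = 50,
                           spindle_dur = 1, so_amp = 75,
                           artifact_spec = NULL, seed = 1L) {
  if (fs < 100) abort("fs must be >= 100 Hz")
  validate_stage_profiles(profiles)
  used <- unique(as.character(hypnogram$stage))
  missing_prof <- setdiff(used, profiles$stage)
  if (length(missing_prof) > 0) {
    abort(sprintf("no stage profile for: %s", paste(missing_prof, collapse = ", ")))
  }
  n_ep <- n_epochs(hypnogram)
  n <- n_ep * EPOCH_SEC * fs
  total_s <- n_ep * EPOCH_SEC
  if (!is.null(artifact_spec)) {
    if (sum(artifact_spec$duration_s) >= total_s) {
      abort("artifact fraction must be < 1")
    }
  }
  set.seed(as.integer(seed))
  edges <- band_edges()
  X <- matrix(0, n, length(channels), dimnames = list(NULL, channels))
  events <- list()

  # contiguous runs of one stage are synthesized as a block
  st <- as.character(hypnogram$stage)
  runs <- rle(st)
  ep0 <- 0L
  for (r in seq_along(runs$lengths)) {
    len_ep <- runs$lengths[r]
    stage <- runs$values[r]
    prof <- profiles[profiles$stage == stage, ]
    i0 <- ep0 * EPOCH_SEC * fs
    nr <- len_ep * EPOCH_SEC * fs
    fr <- c(prof$f_delta, prof$f_theta, prof$f_alpha, prof$f_beta)
    for (ch in seq_along(channels)) {
      sig <- rep(0, nr)
      for (b in seq_along(edges)) {
        sig <- sig + band_noise(nr, fs, edges[[b]][1], edges[[b]][2],
                                target_sd = prof$amplitude_rms * sqrt(fr[b]))
      }
      X[(i0 + 1):(i0 + nr), ch] <- sig
    }
    # spindle bursts (N2) and slow oscillations (N2/N3), same times per channel
    run_t0 <- ep0 * EPOCH_SEC
    if (prof$spindle_rate > 0) {
      k <- rpois(1, prof$spindle_rate * len_ep * EPOCH_SEC / 60)
      if (k > 0) {
        starts <- sort(runif(k, 0, len_ep * EPOCH_SEC - spindle_dur))
        for (s in starts) {
          idx <- i0 + floor(s * fs) + seq_len(round(spindle_dur * fs))
          tt <- (seq_along(idx) - 1) / fs
          burst <- spindle_amp * sin(2 * pi * spindle_freq * tt) *
            (0.5 - 0.5 * cos(2 * pi * tt / spindle_dur))
          X[idx, ] <- X[idx, ] + burst
          events[[length(events) + 1]] <- tibble(
            type = "spindle", start_s = run_t0 + s,
            duration_s = spindle_dur, freq = spindle_freq)
        }
      }
    }
    if (prof$so_rate > 0) {
      k <- rpois(1, prof$so_rate * len_ep * EPOCH_SEC / 60)
      if (k > 0) {
        dur <- runif(k, 1 / 1.2, 1 / 0.8)
        starts <- sort(runif(k, 0, len_ep * EPOCH_SEC - max(dur)))
        for (j in seq_len(k)) {
          idx <- i0 + floor(starts[j] * fs) + seq_len(round(dur[j] * fs))
          tt <- (seq_along(idx) - 1) / fs
          # negative-first full cycle: pos->neg crossings at start and end
          X[idx, ] <- X[idx, ] - so_amp * sin(2 * pi * tt / dur[j])
          events[[length(events) + 1]] <- tibble(
            type = "so", start_s = run_t0 + starts[j],
            duration_s = dur[j], freq = 1 / dur[j])
        }
      }
    }
    ep0 <- ep0 + len_ep
  }

  if (!is.null(artifact_spec)) {
    for (i in seq_len(nrow(artifact_spec))) {
      idx <- floor(artifact_spec$start_s[i] * fs) +
        seq_len(round(artifact_spec$duration_s[i] * fs))
      idx <- idx[idx <= n]
      if (artifact_spec$type[i] == "flat") {
        X[idx, ] <- rnorm(length(idx) * ncol(X), 0, 0.1)
      } else {
        amp_rms <- if ("rms" %in% names(artifact_spec))
          artifact_spec$rms[i] else 300
        X[idx, ] <- rnorm(length(idx) * ncol(X), 0, amp_rms)
      }
    }
  }

  rec <- eeg_record(X, fs = fs, lights_off = 0L, lights_on = n)
  attr(rec, "events") <- if (length(events)) bind_rows(events) else
    tibble(type = character(), start_s = numeric(), duration_s = numeric(),
           freq = numeric())
  attr(rec, "hypnogram") <- hypnogram
  rec
}
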