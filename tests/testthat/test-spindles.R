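n2_record <- function(n_ep = 10, fs = 128, seed = 31, spindle_rate = 0,
                      so_rate = 0) {
  prof <- stage_profiles_default()
  prof$spindle_rate[prof$stage == "N2"] <- spindle_rate
  prof$so_rate[prof$stage == "N2"] <- so_rate
  h <- hypnogram(rep("N2", n_ep))
  rec <- highpass(synthesize_eeg(h, prof, fs = fs, seed = seed))
  list(rec = rec, h = h)
}

hann_burst <- function(fs, dur, freq, amp) {
  tt <- (seq_len(round(dur * fs)) - 1) / fs
  amp * sin(2 * pi * freq * tt) * (0.5 - 0.5 * cos(2 * pi * tt / dur))
}

add_burst <- function(rec, start_s, dur, freq = 13.5, amp = 60,
                      envelope = c("hann", "flat")) {
  envelope <- match.arg(envelope)
  n <- round(dur * rec$fs)
  if (envelope == "hann") {
    b <- hann_burst(rec$fs, dur, freq, amp)
  } else {
    # constant envelope with 0.1-s cosine ramps
    tt <- (seq_len(n) - 1) / rec$fs
    env <- pmin(1, tt / 0.1, (dur - tt) / 0.1)
    b <- amp * sin(2 * pi * freq * tt) * env
  }
  idx <- floor(start_s * rec$fs) + seq_len(n)
  rec$samples[idx, ] <- rec$samples[idx, ] + b
  rec
}

test_that("spindle preparation resamples to 128 Hz", {
  fx <- n2_record(4, fs = 256, seed = 1)
  prep <- prepare_spindle_signal(fx$rec, fx$h)
  expect_equal(prep$fs, 128)
  expect_equal(length(prep$x), nrow(fx$rec$samples) / 2, tolerance = 1)
})

test_that("delta-power epoch rejection matches a sliding-window oracle", {
  fx <- n2_record(20, seed = 3)
  # uniform delta power: nothing rejected
  prep0 <- prepare_spindle_signal(fx$rec, fx$h)
  expect_length(prep0$n2_rejected, 0)

  # one epoch with ~10x delta power gets rejected
  rec <- fx$rec
  fs <- rec$fs
  idx <- (7 * 30 * fs + 1):(8 * 30 * fs)
  tt <- (seq_along(idx) - 1) / fs
  rec$samples[idx, ] <- rec$samples[idx, ] + 150 * sin(2 * pi * 1.5 * tt)
  prep <- prepare_spindle_signal(rec, fx$h)
  expect_identical(prep$n2_rejected, 7L)

  # oracle: recompute delta powers and the 15-epoch sliding means by hand
  bd <- signal::butter(4, c(0.5, 4) / 64, type = "pass")
  xd <- signal::filtfilt(bd, prep$x[1:(20 * 30 * 128)])
  pw <- vapply(1:20, function(k) mean(xd[((k - 1) * 3840 + 1):(k * 3840)]^2), 0)
  loc <- vapply(1:20, function(i) mean(pw[max(1, i - 7):min(20, i + 7)]), 0)
  expect_identical(which(pw > 2.5 * loc) - 1L, 7L)
})

test_that("injected bursts are detected subject to duration rules", {
  fx <- n2_record(10, seed = 5)
  prep1 <- prepare_spindle_signal(add_burst(fx$rec, 100.0, 1.0), fx$h)
  sp1 <- detect_spindles(prep1)
  expect_equal(nrow(sp1), 1)
  expect_true(sp1$start_s < 101 && sp1$end_s > 100)
  expect_true(abs(sp1$freq - 13.5) < 0.7)

  # 0.2-s burst fails the 0.3-s core rule
  prep2 <- prepare_spindle_signal(add_burst(fx$rec, 100.0, 0.2), fx$h)
  expect_equal(nrow(detect_spindles(prep2)), 0)

  # sustained 4-s burst exceeds the 3-s duration cap
  prep3 <- prepare_spindle_signal(
    add_burst(fx$rec, 100.0, 4, envelope = "flat"), fx$h)
  expect_equal(nrow(detect_spindles(prep3)), 0)
})

test_that("detected events never overlap and counts are monotone in the core threshold", {
  fx <- n2_record(10, seed = 7)
  rec <- fx$rec
  for (s in c(20, 50, 51.2, 110, 200)) rec <- add_burst(rec, s, 1.0)
  prep <- prepare_spindle_signal(rec, fx$h)
  sp <- detect_spindles(prep)
  expect_gt(nrow(sp), 1)
  o <- order(sp$start_s)
  gaps <- sp$start_s[o][-1] - sp$end_s[o][-nrow(sp)]
  expect_true(all(gaps >= 0.5 - 1e-9))

  n_hi <- nrow(detect_spindles(prep, core_mult = 8))
  n_lo <- nrow(detect_spindles(prep, core_mult = 3))
  expect_true(n_hi <= nrow(sp) && nrow(sp) <= n_lo)
})

test_that("no N2 yields an empty result with a warning", {
  fx <- n2_record(4, seed = 9)
  prep <- prepare_spindle_signal(fx$rec, fx$h)
  prep$n2_kept <- integer(0)
  expect_warning(sp <- detect_spindles(prep), "no N2")
  expect_equal(nrow(sp), 0)
})

test_that("slow-oscillation crossings follow the closed-form intervals", {
  fs <- 128
  make_prep <- function(freq) {
    t <- seq(0, 60 - 1 / fs, by = 1 / fs)
    structure(list(x = 40 * sin(2 * pi * freq * t), fs = fs,
                   hypnogram = hypnogram(rep("N2", 2)), channel = "C3",
                   n2_kept = 0:1, n2_rejected = integer(0)),
              class = "spindle_signal")
  }
  so1 <- detect_slow_oscillations(make_prep(1))
  expect_gt(nrow(so1), 40)
  expect_true(all(abs((so1$end_s - so1$start_s) - 1.0) < 0.02))

  expect_equal(nrow(detect_slow_oscillations(make_prep(3))), 0)   # 0.33 s
  expect_equal(nrow(detect_slow_oscillations(make_prep(0.4))), 0) # 2.5 s
})

test_that("coupling phase is the linear position of the peak inside the SO", {
  sos <- tibble::tibble(channel = "C3", start_s = 10, end_s = 12)
  sp <- tibble::tibble(channel = "C3", start_s = c(10.8, 9.9, 10.3, 5),
                       end_s = c(11.2, 10.3, 10.7, 5.4),
                       peak_s = c(11, 10, 10.5, 5.2),
                       freq = 13.5, class = "fast")
  out <- couple_and_phase(sp, sos)
  expect_equal(out$phase_deg[1], 180)
  expect_equal(out$phase_deg[2], 0)
  expect_equal(out$phase_deg[3], 90)
  expect_true(is.na(out$phase_deg[4]))   # uncoupled spindle carries no phase
})

test_that("phase of bursts injected at known SO fractions is recovered", {
  fs <- 128
  set.seed(15)
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  x <- 60 * sin(2 * pi * 1 * t) + rnorm(length(t), 0, 3)
  # pos->neg crossings of the 1 Hz carrier at t = 0.5, 1.5, ...; inject a
  # burst peaking 25% into the SO starting at 20.5 s
  burst <- hann_burst(fs, 0.5, 13.5, 60)
  center <- 20.75
  idx <- floor((center - 0.25) * fs) + seq_along(burst)
  x[idx] <- x[idx] + burst
  prep <- structure(list(x = x, fs = fs, hypnogram = hypnogram(rep("N2", 4)),
                         channel = "C3", n2_kept = 0:3,
                         n2_rejected = integer(0)),
                    class = "spindle_signal")
  sp <- detect_spindles(prep)
  expect_equal(nrow(sp), 1)
  out <- couple_and_phase(sp, detect_slow_oscillations(prep))
  expect_false(is.na(out$phase_deg[1]))
  expect_lt(abs(out$phase_deg[1] - 90), 10)
})

test_that("density, dispersion and phase summaries match hand computations", {
  # 10 spindles across 10 N2 epochs (5 minutes) -> density 2/min
  sp <- tibble::tibble(channel = "C3",
                       start_s = c(5, 40, 70, 100, 130, 160, 190, 220, 250, 280),
                       end_s = start_s + 1, peak_s = start_s + 0.5,
                       freq = 13.5, class = "fast", phase_deg = 90)
  f <- spindle_features(sp, 0:9)
  expect_equal(f$density, 2)
  expect_equal(f$phase_fast_deg, 90)
  expect_true(is.na(f$phase_slow_deg))

  # equal per-epoch counts -> dispersion 0
  sp2 <- tibble::tibble(channel = "C3", start_s = c(2, 10, 32, 40),
                        end_s = start_s + 1, peak_s = start_s + 0.5,
                        freq = 12, class = "slow")
  expect_equal(spindle_features(sp2, 0:1)$dispersion, 0)

  # per-epoch counts (0,1,2,3): population variance 1.25, mean 1.5
  starts <- c(31, 61, 65, 91, 95, 99)
  sp3 <- tibble::tibble(channel = "C3", start_s = starts,
                        end_s = starts + 1, peak_s = starts + 0.5,
                        freq = 14, class = "fast")
  expect_equal(spindle_features(sp3, 0:3)$dispersion, 1.25 / 1.5)

  # zero spindles: density 0, dispersion and phases missing
  f0 <- spindle_features(sp3[0, ], 0:3)
  expect_equal(f0$density, 0)
  expect_true(is.na(f0$dispersion))
})
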