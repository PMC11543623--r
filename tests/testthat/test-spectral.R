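test_that("DPSS tapers are orthonormal", {
  V <- dpss_tapers(256, nw = 2, k = 3)
  G <- t(V) %*% V
  expect_equal(unname(G), diag(3), tolerance = 1e-8)
  expect_error(dpss_tapers(4, k = 5), "fewer tapers")
})

test_that("pure tones concentrate power in the right band", {
  fs <- 128
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  bp2 <- multitaper_bandpowers(sin(2 * pi * 2 * t), fs)
  tot <- rowSums(bp2[, c("delta", "theta", "alpha", "beta")])
  expect_true(all(bp2$delta / tot >= 0.95))

  bp10 <- multitaper_bandpowers(sin(2 * pi * 10 * t), fs)
  tot10 <- rowSums(bp10[, c("delta", "theta", "alpha", "beta")])
  expect_true(all(bp10$alpha / tot10 > 0.9))
})

test_that("white-noise band powers scale with bandwidth", {
  set.seed(11)
  fs <- 128
  bp <- multitaper_bandpowers(rnorm(600 * fs), fs)
  m <- colMeans(bp[, c("delta", "theta", "alpha", "beta")])
  # flat spectrum: power proportional to band widths 3.5 : 4 : 4 : 18
  ratio <- m / c(3.5, 4, 4, 18)
  expect_lt(diff(range(ratio)) / mean(ratio), 0.1)
})

test_that("multitaper total power approximates signal variance in band", {
  set.seed(13)
  fs <- 128
  x <- rnorm(120 * fs)
  bp <- multitaper_bandpowers(x, fs)
  tot <- mean(rowSums(bp[, c("delta", "theta", "alpha", "beta")]))
  # unit-variance white noise: fraction of variance in 0.5-30 Hz
  expected <- (30 - 0.5) / (fs / 2)
  expect_equal(tot, expected, tolerance = 0.15)
})

test_that("relative power normalises and rejects zero totals", {
  expect_equal(unname(relative_power(c(delta = 1, theta = 1, alpha = 1,
                                       beta = 1))),
               rep(0.25, 4))
  expect_equal(unname(relative_power(c(delta = 3, theta = 1, alpha = 0,
                                       beta = 0))),
               c(0.75, 0.25, 0, 0))
  set.seed(2)
  r <- relative_power(runif(4, 0.1, 5))
  expect_equal(sum(r), 1, tolerance = 1e-12)
  expect_error(relative_power(c(delta = 0, theta = 0, alpha = 0, beta = 0)),
               "excluded")
})

test_that("epoch aggregation averages surviving windows only", {
  fs <- 128
  win <- tibble::tibble(start_s = 0:28,
                        delta = 1:29, theta = 1, alpha = 1, beta = 1)
  emap <- tibble::tibble(epoch = 0L, stage = factor("N2", stages5),
                         start_sample = 0L, end_sample = 30L * fs,
                         segments = list(0:9))
  agg <- aggregate_to_epochs(win, emap)
  expect_equal(agg$n_windows, 29L)
  expect_equal(agg$delta, mean(1:29))   # brute-force mean of hop windows

  mask <- tibble::tibble(segment = 0L, channel = "C3", rms = 300,
                         flagged = TRUE)
  agg2 <- aggregate_to_epochs(win, emap, mask)
  # windows overlapping segment 0 ([0,3) s) start at 0, 1, 2
  expect_equal(agg2$n_windows, 26L)
  expect_equal(agg2$delta, mean(4:29))

  mask_all <- tibble::tibble(segment = 0:9, channel = "C3", rms = 300,
                             flagged = TRUE)
  agg3 <- aggregate_to_epochs(win, emap, mask_all)
  expect_equal(agg3$n_windows, 0L)
  expect_true(is.na(agg3$delta))
})

test_that("stage features are epoch means of relative power, then log", {
  ep <- tibble::tibble(
    epoch = 0:1, stage = factor("N2", stages5), n_windows = 29L,
    delta = c(0.4, 0.6), theta = c(0.3, 0.2), alpha = c(0.2, 0.1),
    beta = c(0.1, 0.1))
  sf <- stage_features(ep)
  n2delta <- dplyr::filter(sf, stage == "N2", band == "delta")
  expect_equal(n2delta$rel_power, 0.5)
  expect_equal(n2delta$log_rel_power, log(0.5))
  # absent stage is missing, not zero
  expect_true(all(is.na(dplyr::filter(sf, stage == "REM")$rel_power)))
  expect_equal(unique(dplyr::filter(sf, stage == "REM")$n_epochs), 0L)

  one <- stage_features(ep[1, ])
  expect_equal(dplyr::filter(one, stage == "N2", band == "theta")$log_rel_power,
               log(0.3))
})

test_that("relative powers are invariant to amplitude scaling", {
  h <- hypnogram(rep("W", 4))
  rec <- highpass(synthesize_eeg(h, fs = 128, seed = 21))
  rec10 <- rec
  rec10$samples <- rec10$samples * 10
  # disable amplitude-based masking: scaling is a gain change, not an artifact
  no_mask <- function(r) reject_artifacts_rms(r, lo = 0, hi = Inf)
  f1 <- spectral_features(rec, h, mask = no_mask(rec))
  f2 <- spectral_features(rec10, h, mask = no_mask(rec10))
  expect_equal(f1$rel_power, f2$rel_power, tolerance = 1e-9)
})

test_that("the spectral pipeline recovers configured band fractions", {
  prof <- stage_profiles_default()
  h <- hypnogram(rep("N3", 10))   # 5 minutes of N3
  rec <- highpass(synthesize_eeg(h, prof, fs = 128, seed = 23))
  sf <- dplyr::filter(spectral_features(rec, h), stage == "N3")
  target <- unlist(prof[prof$stage == "N3",
                        c("f_delta", "f_theta", "f_alpha", "f_beta")])
  got <- sf$rel_power[match(c("delta", "theta", "alpha", "beta"), sf$band)]
  expect_true(all(abs(got - target) < 0.1))
})

test_that("too-short segments yield an empty warning result", {
  expect_warning(out <- multitaper_bandpowers(rnorm(100), 128), "shorter")
  expect_equal(nrow(out), 0)
})
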