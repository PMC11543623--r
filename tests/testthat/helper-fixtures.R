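stages5 <- somnarch::sleep_stages()

named_matrix <- function(x) {
  matrix(x, nrow = 5, byrow = TRUE,
         dimnames = list(from = stages5, to = stages5))
}

uniform_matrix <- function() named_matrix(rep(0.2, 25))

# plausible overnight transition matrix used across transition tests
test_baseline_matrix <- function() {
  named_matrix(c(
    0.880, 0.070, 0.020, 0.005, 0.025,
    0.250, 0.350, 0.350, 0.010, 0.040,
    0.040, 0.050, 0.840, 0.040, 0.030,
    0.020, 0.010, 0.120, 0.840, 0.010,
    0.040, 0.040, 0.050, 0.005, 0.865))
}

# single-feature spec with controllable variance components
one_feature_spec <- function(feature = "wake_rel_delta", grand_mean = 35,
                             subject_sd = 4, site_sd = 1, residual_sd = 2.5,
                             drift_m1 = 0, drift_m3 = 0, night_effect = 0) {
  tibble::tibble(feature = feature, grand_mean = grand_mean,
                 drift_m1 = drift_m1, drift_m3 = drift_m3,
                 subject_sd = subject_sd, site_sd = site_sd,
                 residual_sd = residual_sd, night_effect = night_effect)
}

# fit wrapper silencing the expected singular-fit fallback warning on
# zero-variance designs
quiet_fit <- function(...) suppressWarnings(fit_null_and_main(...))

# separable synthetic WESI feature clouds: wake has high alpha+beta,
# sleep has high delta
make_wesi_clouds <- function(n_per_class = 200, sep = 0.25, seed = 1) {
  set.seed(seed)
  jitter4 <- function(base, n) {
    # rnorm recycles the 4 base means elementwise, so fill row-wise
    r <- matrix(abs(rnorm(4 * n, base, 0.03)), ncol = 4, byrow = TRUE)
    sweep(r, 1, rowSums(r), "/")
  }
  wake <- jitter4(c(0.20, 0.15, 0.35 + sep / 2, 0.30), n_per_class)
  sleep <- jitter4(c(0.55 + sep / 2, 0.25, 0.10, 0.10), n_per_class)
  m <- rbind(wake, sleep)
  tibble::tibble(label = rep(c(1L, 0L), each = n_per_class),
                 stage = rep(c("W", "N3"), each = n_per_class),
                 r_delta = m[, 1], r_theta = m[, 2],
                 r_alpha = m[, 3], r_beta = m[, 4])
}
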