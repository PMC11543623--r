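test_that("zero-noise cohorts are recovered exactly by the mixed models", {
  des <- cohort_design(c(placebo = 6, `25` = 6, `50` = 6), n_sites = 3,
                       seed = 4)
  spec <- one_feature_spec(subject_sd = 0, site_sd = 0, residual_sd = 0,
                           drift_m3 = 0.7)
  # zero effect: contrast exactly 0
  co0 <- simulate_feature_cohort(des, spec)
  fit0 <- quiet_fit(co0)
  expect_equal(treatment_contrast(fit0, "50", 3)$estimate, 0,
               tolerance = 1e-8)

  # injected delta: contrast exactly d
  co <- simulate_feature_cohort(des, spec,
                                effect_spec("wake_rel_delta", "50", 3, 2.5))
  fit <- quiet_fit(co)
  ct <- treatment_contrast(fit, "50", 3)
  expect_equal(ct$estimate, 2.5, tolerance = 1e-6)
  expect_true(ct$conf.low <= ct$estimate && ct$estimate <= ct$conf.high)
  expect_error(treatment_contrast(fit, "10", 3), "absent")
})

test_that("main model log-likelihood dominates the null (nesting)", {
  des <- cohort_design(c(placebo = 10, `50` = 10), n_sites = 3, seed = 6)
  for (s in 1:3) {
    des$seed <- s
    co <- simulate_feature_cohort(des, one_feature_spec())
    g <- glance(quiet_fit(co))
    expect_gte(g$logLik_main, g$logLik_null - 1e-6)
    expect_gte(g$lrt_stat, 0)
  }
})

test_that("stochastic injected effects are recovered without material bias", {
  # moderate-noise recovery at small n, averaged over replicates
  ests <- vapply(1:8, function(r) {
    des <- cohort_design(c(placebo = 40, `50` = 40), n_sites = 4, seed = 100 + r)
    co <- simulate_feature_cohort(
      des, one_feature_spec(subject_sd = 2, site_sd = 0.5, residual_sd = 1.5),
      effect_spec("wake_rel_delta", "50", c(1, 3), c(2, 2)))
    fit <- quiet_fit(co, lrt = FALSE)
    treatment_contrast(fit, "50", 3)$estimate
  }, 0)
  expect_lt(abs(mean(ests) - 2), 0.25)
})

test_that("transition model selection follows the prevalence rules", {
  expect_equal(select_transition_model(0.01), "excluded")
  expect_equal(select_transition_model(0.5), "hurdle")
  expect_equal(select_transition_model(0.99), "glmm")
  expect_equal(select_transition_model(0.015), "hurdle")
  expect_equal(select_transition_model(0.985), "hurdle")
  expect_error(select_transition_model(1.2))
})

test_that("hurdle zero stage reproduces the marginal zero rate", {
  set.seed(33)
  des <- cohort_design(c(placebo = 50, `50` = 50), n_sites = 4, seed = 7)
  rows <- cohort_rows(des)
  rows$opportunities <- 199L
  rows$count <- rpois(nrow(rows), 3) * rbinom(nrow(rows), 1, 0.7)
  hf <- fit_hurdle(rows)
  expect_s3_class(hf, "hurdle_fit")
  expect_equal(mean(predict(hf$zero, type = "response")),
               mean(rows$count == 0), tolerance = 0.02)
  td <- tidy(hf)
  expect_true(all(c("zero", "nonzero") %in% td$stage))

  rows$count <- rpois(nrow(rows), 2) + 1L
  expect_error(fit_hurdle(rows), "select_transition_model")
})

test_that("hurdle nonzero stage detects an injected count reduction", {
  set.seed(44)
  des <- cohort_design(c(placebo = 80, `50` = 80), n_sites = 4, seed = 8)
  rows <- cohort_rows(des)
  rows$opportunities <- 199L
  lam <- ifelse(rows$treatment == "50" & rows$month == 3, 3, 6)
  rows$count <- rpois(nrow(rows), lam) * rbinom(nrow(rows), 1, 0.85)
  hf <- fit_hurdle(rows)
  td <- dplyr::filter(tidy(hf), stage == "nonzero",
                      term == "month3:treatment50")
  expect_lt(td$estimate, 0)
  expect_lt(td$statistic, -2)
})

test_that("BH correction matches hand computation within families", {
  r <- tibble::tibble(family = "spectral", p = c(0.01, 0.02, 0.03, 0.04),
                      contrast_p = c(0.01, 0.2, 0.01, 0.01))
  out <- fdr_correct(r)
  expect_equal(out$q, rep(0.04, 4))
  expect_equal(out$significant, c(TRUE, FALSE, TRUE, TRUE))

  one <- fdr_correct(tibble::tibble(family = "WESI", p = 0.03))
  expect_equal(one$q, 0.03)
  all1 <- fdr_correct(tibble::tibble(family = "spindle", p = rep(1, 5)))
  expect_equal(all1$q, rep(1, 5))
  empty <- fdr_correct(tibble::tibble(family = character(), p = numeric()))
  expect_equal(nrow(empty), 0)
})

test_that("BH q-values are monotone in p and order-invariant", {
  set.seed(3)
  p <- runif(12)
  r <- tibble::tibble(family = "spectral", p = p)
  q1 <- fdr_correct(r)$q
  perm <- sample(12)
  q2 <- fdr_correct(r[perm, ])$q
  expect_equal(q2, q1[perm])
  expect_true(all(diff(q1[order(p)]) >= -1e-12))
  # families are corrected independently
  r2 <- tibble::tibble(family = rep(c("spectral", "WESI"), each = 3),
                       p = c(0.01, 0.02, 0.03, 0.01, 0.02, 0.03))
  q <- fdr_correct(r2)$q
  expect_equal(q[1:3], q[4:6])
})

test_that("logit back-transform agrees with a 10k bootstrap within 0.001", {
  expect_equal(wesi_linear_scale(0, 0.1)$mean, 0.5)
  out <- wesi_linear_scale(1.2, 0.03, bootstrap = TRUE, seed = 5)
  expect_lt(abs(out$conf.low - out$boot.low), 0.001)
  expect_lt(abs(out$conf.high - out$boot.high), 0.001)
  # monotone in the logit mean
  m <- vapply(c(-1, 0, 1, 2), function(e) wesi_linear_scale(e, 0.1)$mean, 0)
  expect_true(all(diff(m) > 0))
})
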