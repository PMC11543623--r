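test_that("Markov simulation honours absorbing and deterministic matrices", {
  I5 <- named_matrix(as.numeric(diag(5)))
  h <- simulate_hypnogram(I5, 10, "W", seed = 1)
  expect_equal(as.character(h$stage), rep("W", 10))

  cyc <- named_matrix(rep(0, 25))
  cyc["W", "N1"] <- 1
  cyc["N1", "W"] <- 1
  cyc["N2", "N2"] <- 1; cyc["N3", "N3"] <- 1; cyc["REM", "REM"] <- 1
  h2 <- simulate_hypnogram(cyc, 4, "W", seed = 1)
  expect_equal(as.character(h2$stage), c("W", "N1", "W", "N1"))
})

test_that("empirical transition frequencies converge to the generating matrix", {
  h <- simulate_hypnogram(uniform_matrix(), 1e5, seed = 4)
  # brute-force count check, independent of transition_counts()
  st <- as.integer(h$stage)
  emp <- table(factor(st[-1e5], 1:5), factor(st[-1], 1:5)) / (1e5 - 1)
  probs <- sweep(emp, 1, rowSums(emp), "/")
  expect_true(all(abs(probs - 0.2) < 0.01))
})

test_that("invalid matrices and stages are rejected", {
  bad <- uniform_matrix(); bad[1, 1] <- 0.5
  expect_error(simulate_hypnogram(bad, 10), "sum to 1")
  expect_error(simulate_hypnogram(uniform_matrix(), 10, "QQ"), "unknown")
  expect_error(simulate_hypnogram(uniform_matrix(), 1), "n_epochs")
})

test_that("matrix perturbation preserves row-stochasticity or fails loudly", {
  P <- test_baseline_matrix()
  d <- tibble::tibble(from = c("W", "W"), to = c("W", "N1"),
                      delta = c(-0.05, 0.05))
  P2 <- perturb_transition_matrix(P, d)
  expect_equal(rowSums(P2), rowSums(P))
  expect_equal(P2["W", "W"], P["W", "W"] - 0.05)

  set.seed(3)
  for (i in 1:20) {
    eps <- runif(1, 0, 0.05)
    dd <- tibble::tibble(from = "N1", to = c("N1", "N2"),
                         delta = c(-eps, eps))
    expect_equal(unname(rowSums(perturb_transition_matrix(P, dd))),
                 rep(1, 5), tolerance = 1e-12)
  }

  expect_error(perturb_transition_matrix(
    P, tibble::tibble(from = "W", to = "N3", delta = -0.2)), "outside")
  expect_error(perturb_transition_matrix(
    P, tibble::tibble(from = "W", to = "N1", delta = 0.05)), "sum to zero")
})

test_that("fixed seeds make hypnogram and cohort simulation reproducible", {
  h1 <- simulate_hypnogram(test_baseline_matrix(), 200, seed = 77)
  h2 <- simulate_hypnogram(test_baseline_matrix(), 200, seed = 77)
  expect_identical(h1, h2)

  des <- cohort_design(c(placebo = 4, `50` = 4), n_sites = 2, seed = 5)
  co1 <- simulate_feature_cohort(des, one_feature_spec())
  co2 <- simulate_feature_cohort(des, one_feature_spec())
  expect_identical(co1$value, co2$value)

  tc1 <- simulate_transition_cohort(des, test_baseline_matrix(),
                                    n_epochs = 50, seed = 3)
  tc2 <- simulate_transition_cohort(des, test_baseline_matrix(),
                                    n_epochs = 50, seed = 3)
  expect_identical(tc1$hypnograms, tc2$hypnograms)
})

test_that("zero-variance feature cohorts are exactly deterministic", {
  des <- cohort_design(c(placebo = 5, `50` = 5), n_sites = 2, seed = 2)
  spec <- one_feature_spec(subject_sd = 0, site_sd = 0, residual_sd = 0,
                           drift_m1 = 0.5, drift_m3 = 1.25)
  co <- simulate_feature_cohort(des, spec)
  expect_equal(unique(co$value[co$month == 0]), 35)
  expect_equal(unique(co$value[co$month == 1]), 35.5)
  expect_equal(unique(co$value[co$month == 3]), 36.25)
})

test_that("injected deltas appear exactly as difference-in-differences", {
  des <- cohort_design(c(placebo = 5, `50` = 5), n_sites = 2, seed = 2)
  spec <- one_feature_spec(subject_sd = 0, site_sd = 0, residual_sd = 0,
                           drift_m3 = 1.1)
  co <- simulate_feature_cohort(des, spec,
                                effect_spec("wake_rel_delta", "50", 3, 4.33))
  cellm <- function(arm, mo) mean(co$value[co$treatment == arm & co$month == mo])
  did <- (cellm("50", 3) - cellm("50", 0)) -
    (cellm("placebo", 3) - cellm("placebo", 0))
  expect_equal(did, 4.33)
})

test_that("effect specifications are validated", {
  des <- cohort_design(c(placebo = 3, `50` = 3), n_sites = 2, seed = 1)
  expect_error(effect_spec("x", "50", 0, 1), "baseline")
  expect_error(effect_spec("x", "placebo", 3, 1), "placebo")
  expect_error(
    simulate_feature_cohort(des, one_feature_spec(),
                            effect_spec("nope", "50", 3, 1)),
    "unknown feature")
  expect_error(
    simulate_transition_cohort(
      des, test_baseline_matrix(),
      tibble::tibble(treatment = "50", month = 0, from = "W", to = "N1",
                     delta = 0.01),
      n_epochs = 20),
    "baseline")
})

test_that("transition cohorts with zero deltas have matching arm-level matrices", {
  des <- cohort_design(c(placebo = 20, `50` = 20), n_sites = 2,
                       visits = c(0, 3), seed = 8)
  tc <- simulate_transition_cohort(des, test_baseline_matrix(),
                                   n_epochs = 400, seed = 12)
  pr <- cohort_transition_probabilities(tc)
  did <- transition_did(pr, "W", "W", "50", 3)
  expect_lt(abs(did), 0.03)
})

test_that("hypnogram text round-trips through the TSV dialect", {
  h <- simulate_hypnogram(test_baseline_matrix(), 40, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hypnogram(h, path)
  expect_identical(read_hypnogram(path)$stage, h$stage)
})
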