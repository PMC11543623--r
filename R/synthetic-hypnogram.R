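#' Simulate a hypnogram from a first-order Markov chain
#'
#' Draws a stage sequence of `n_epochs` 30-second epochs from a 5x5
#' row-stochastic transition matrix, the generative counterpart of the
#' transition-count analysis: empirical transition frequencies of the output
#' converge to the matrix as `n_epochs` grows.
#'
#' @param transition_matrix 5x5 row-stochastic matrix over [sleep_stages()]
#'   (rows = from, columns = to; each row sums to 1 within 1e-9).
#' @param n_epochs Number of epochs to draw (>= 2).
#' @param initial_stage Stage label of the first epoch, default `"W"`
#'   (lights-off).
#' @param seed Optional integer seed for reproducibility.
#' @return A [hypnogram()].
#' @export
#' @examples
#' P <- diag(5); dimnames(P) <- list(sleep_stages(), sleep_stages())
#' simulate_hypnogram(P, 10, "W") # absorbing: all W
simulate_hypnogram <- function(transition_matrix, n_epochs,
                               initial_stage = "W", seed = NULL) {
  m <- simulate_hypnogram_matrix(transition_matrix, n_epochs, n_chains = 1L,
                                 initial_stage = initial_stage, seed = seed)
  hypnogram(sleep_stages()[m[1L, ]])
}

# Vectorised Markov engine: simulates n_chains stage sequences at once.
# Returns an integer matrix (n_chains x n_epochs) of stage indices 1..5.
# The epoch loop is vectorised over chains so cohort-scale simulation
# (thousands of nights x ~1000 epochs) stays fast in plain R.
simulate_hypnogram_matrix <- function(transition_matrix, n_epochs, n_chains,
                                      initial_stage = "W", seed = NULL) {
  assert_row_stochastic(transition_matrix)
  if (n_epochs < 2) abort("n_epochs must be >= 2")
  assert_stages(initial_stage, "initial stage")
  if (!is.null(seed)) set.seed(as.integer(seed))
  # row-wise cumulative probabilities; guard the last column against
  # accumulated rounding so inversion sampling never falls off the end
  cum <- t(apply(transition_matrix, 1, cumsum))
  cum[, 5] <- 1
  S <- matrix(0L, nrow = n_chains, ncol = n_epochs)
  S[, 1] <- match(initial_stage, sleep_stages())
  for (t in seq_len(n_epochs - 1L)) {
    u <- runif(n_chains)
    cur <- S[, t]
    nxt <- 1L +
      (u > cum[cur, 1]) + (u > cum[cur, 2]) +
      (u > cum[cur, 3]) + (u > cum[cur, 4])
    S[, t + 1L] <- as.integer(nxt)
  }
  S
}

#' Perturb a transition matrix by cell-wise deltas
#'
#' Adds signed deltas (probability units) to named cells of a row-stochastic
#' matrix. Deltas must sum to zero within each row; a perturbation driving
#' any entry outside \[0, 1\] is an error. Used to inject placebo-corrected
#' treatment effects on transition probabilities.
#'
#' @param P 5x5 row-stochastic matrix.
#' @param deltas Tibble/data frame with columns `from`, `to`, `delta`.
#' @return Perturbed row-stochastic matrix.
#' @export
perturb_transition_matrix <- function(P, deltas) {
  assert_row_stochastic(P)
  out <- P
  if (nrow(deltas) > 0) {
    assert_stages(c(deltas$from, deltas$to))
    idx <- cbind(match(deltas$from, sleep_stages()),
                 match(deltas$to, sleep_stages()))
    out[idx] <- out[idx] + deltas$delta
  }
  if (any(out < -1e-12 | out > 1 + 1e-12)) {
    abort("perturbation drives a transition probability outside [0, 1]")
  }
  out <- pmin(pmax(out, 0), 1)
  if (any(abs(rowSums(out) - 1) > 1e-9)) {
    abort("perturbation deltas must sum to zero within each row")
  }
  out
}

#' Simulate a transition-tier cohort of hypnograms
#'
#' Draws per-recording hypnograms for a multi-arm, multi-visit design from
#' arm/visit-specific transition matrices: the baseline matrix, perturbed by
#' the injected deltas for treated arms at post-baseline visits. Ground-truth
#' matrices are retained in the result so recovery can be checked exactly.
#'
#' @param design A [cohort_design()].
#' @param baseline_matrix 5x5 row-stochastic baseline transition matrix.
#' @param arm_month_deltas Tibble with columns `treatment`, `month`, `from`,
#'   `to`, `delta`: the injected placebo-corrected probability changes.
#'   Deltas at baseline (`month == 0`) are an error.
#' @param n_epochs Epochs per night (default 960 = 8 h).
#' @param seed Integer seed.
#' @return An object of class `transition_cohort`: a list with `design`
#'   (tibble, one row per recording), `hypnograms` (list of [hypnogram()]s)
#'   and `truth` (list of per arm x month matrices).
#' @export
simulate_transition_cohort <- function(design, baseline_matrix,
                                       arm_month_deltas = NULL,
                                       n_epochs = 960L, seed = 1L) {
  assert_row_stochastic(baseline_matrix)
  if (!is.null(arm_month_deltas) && nrow(arm_month_deltas) > 0 &&
      any(arm_month_deltas$month == 0)) {
    abort("effects cannot be injected at baseline (month 0)")
  }
  rows <- cohort_rows(design)
  truth <- list()
  hyps <- vector("list", nrow(rows))
  groups <- dplyr::group_split(group_by(rows, .data$treatment, .data$month))
  k <- 0L
  for (g in groups) {
    arm <- g$treatment[1]
    mo <- g$month[1]
    d <- if (is.null(arm_month_deltas)) NULL else
      filter(arm_month_deltas, .data$treatment == arm, .data$month == mo)
    P <- if (is.null(d) || nrow(d) == 0) baseline_matrix else
      perturb_transition_matrix(baseline_matrix, d)
    truth[[paste(arm, mo, sep = "_")]] <- P
    k <- k + 1L
    S <- simulate_hypnogram_matrix(P, n_epochs, n_chains = nrow(g),
                                   seed = child_seed(seed, k))
    pos <- match(g$recording_id, rows$recording_id)
    for (i in seq_len(nrow(g))) {
      hyps[[pos[i]]] <- hypnogram(sleep_stages()[S[i, ]])
    }
  }
  structure(list(design = rows, hypnograms = hyps, truth = truth),
            class = "transition_cohort")
}

#' @exportS3Method base::print
print.transition_cohort <- function(x, ...) {
  cat(sprintf("<transition_cohort> %d recordings, %d epochs/night\n",
              nrow(x$design), n_epochs(x$hypnograms[[1]])))
  invisible(x)
}
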