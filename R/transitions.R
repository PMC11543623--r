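#' Sleep-wake stage transition counts
#'
#' Counts transitions between consecutive 30-second epochs of a hypnogram,
#' self-transitions included, giving the 5x5 count matrix of a first-order
#' Markov model of sleep-wake dynamics. With `n` epochs the matrix holds
#' exactly `n - 1` counts.
#'
#' @param h A [hypnogram()] with at least two epochs.
#' @return A 5x5 integer matrix with `dimnames` over [sleep_stages()],
#'   rows = from-stage, columns = to-stage.
#' @export
#' @examples
#' transition_counts(hypnogram(c("W", "W", "N1", "N2")))
transition_counts <- function(h) {
  if (!inherits(h, "hypnogram")) h <- hypnogram(h)
  n <- n_epochs(h)
  if (n < 2) abort("need at least 2 epochs to count transitions")
  from <- as.integer(h$stage[-n])
  to <- as.integer(h$stage[-1])
  counts <- matrix(
    tabulate((from - 1L) * 5L + to, nbins = 25L),
    nrow = 5, byrow = TRUE,
    dimnames = list(from = sleep_stages(), to = sleep_stages())
  )
  storage.mode(counts) <- "integer"
  counts
}

#' Row-normalise a transition count matrix
#'
#' Divides each row of a 5x5 transition count matrix by its row sum to obtain
#' first-order Markov transition probabilities. Rows for stages that never
#' occur as a from-stage have no data and are returned as `NA` (missing), not
#' zero.
#'
#' @param counts 5x5 count matrix from [transition_counts()].
#' @return 5x5 numeric matrix; occupied rows sum to 1, unoccupied rows are
#'   `NA`.
#' @export
transition_probabilities <- function(counts) {
  if (!is.matrix(counts) || any(dim(counts) != 5)) {
    abort("counts must be a 5x5 matrix")
  }
  if (any(counts < 0)) abort("counts must be non-negative")
  rs <- rowSums(counts)
  if (all(rs == 0)) abort("all rows empty: no transitions observed")
  P <- counts / ifelse(rs > 0, rs, NA_real_)
  P[rs == 0, ] <- NA_real_
  dimnames(P) <- list(from = sleep_stages(), to = sleep_stages())
  P
}

#' Tidy long-format view of a transition matrix
#'
#' @param counts 5x5 count matrix.
#' @param recording_id Optional identifier column value.
#' @return Tibble with columns `recording_id` (if given), `from`, `to`,
#'   `count`, `probability`.
#' @export
tidy_transitions <- function(counts, recording_id = NULL) {
  P <- transition_probabilities(counts)
  out <- tibble(
    from = rep(sleep_stages(), each = 5),
    to = rep(sleep_stages(), times = 5),
    count = as.integer(as.vector(t(counts))),
    probability = as.vector(t(P))
  )
  if (!is.null(recording_id)) {
    out <- mutate(out, recording_id = recording_id, .before = 1)
  }
  out
}

#' Per-recording transition probabilities for a simulated cohort
#'
#' Computes the empirical transition probability matrix of every recording in
#' a transition-tier cohort (see [simulate_transition_cohort()]) and returns
#' them in long format joined to the design columns. Cohort-level summaries
#' average per-recording probabilities, matching the per-recording modelling
#' unit of the statistical layer.
#'
#' @param cohort A `transition_cohort` from [simulate_transition_cohort()].
#' @return Tibble, one row per recording x from x to, with the design columns
#'   and `probability`.
#' @export
cohort_transition_probabilities <- function(cohort) {
  stopifnot(inherits(cohort, "transition_cohort"))
  pmat <- vapply(cohort$hypnograms, function(h) {
    as.vector(t(transition_probabilities(transition_counts(h))))
  }, numeric(25))
  probs <- tibble(
    recording_id = rep(cohort$design$recording_id, each = 25),
    from = rep(rep(sleep_stages(), each = 5), times = ncol(pmat)),
    to = rep(sleep_stages(), times = 5 * ncol(pmat)),
    probability = as.vector(pmat)
  )
  left_join(probs, cohort$design, by = "recording_id")
}

#' Placebo-corrected difference-in-differences of transition probabilities
#'
#' For one transition cell, computes (arm change from baseline) minus
#' (placebo change from baseline) of the mean per-recording empirical
#' transition probability at a given visit month.
#'
#' @param probs Output of [cohort_transition_probabilities()].
#' @param from,to Stage labels of the transition cell.
#' @param arm Treated arm label (e.g. `"50"`).
#' @param month Visit month (1 or 3).
#' @param reference Reference arm, default `"placebo"`.
#' @return Single numeric: placebo-corrected change in probability.
#' @export
transition_did <- function(probs, from, to, arm, month, reference = "placebo") {
  assert_stages(c(from, to))
  cell <- filter(probs, .data$from == !!from, .data$to == !!to)
  mean_cell <- function(a, m) {
    mean(filter(cell, .data$treatment == a, .data$month == m)$probability,
         na.rm = TRUE)
  }
  (mean_cell(arm, month) - mean_cell(arm, 0)) -
    (mean_cell(reference, month) - mean_cell(reference, 0))
}
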