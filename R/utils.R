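#' Canonical sleep stage labels
#'
#' The five AASM stages used throughout: wake, N1, N2, N3 and REM, in this
#' fixed order. All stage factors, transition matrices and stage profiles are
#' indexed by these labels.
#'
#' @return Character vector of length five.
#' @export
#' @examples
#' sleep_stages()
sleep_stages <- function() c("W", "N1", "N2", "N3", "REM")

# epoch length fixed by AASM scoring; segments are the artifact/WESI grid
EPOCH_SEC <- 30
SEGMENT_SEC <- 3

assert_stages <- function(x, what = "stage labels") {
  bad <- setdiff(unique(as.character(x)), sleep_stages())
  if (length(bad) > 0) {
    abort(sprintf("unknown %s: %s", what, paste(bad, collapse = ", ")))
  }
  invisible(x)
}

assert_row_stochastic <- function(P, tol = 1e-9) {
  if (!is.matrix(P) || nrow(P) != 5L || ncol(P) != 5L) {
    abort("transition matrix must be 5x5 over stages W, N1, N2, N3, REM")
  }
  if (any(P < -tol) || any(P > 1 + tol)) {
    abort("transition probabilities must lie in [0, 1]")
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-9)) {
    abort("each transition-matrix row must sum to 1 (within 1e-9)")
  }
  invisible(P)
}

#' Logit and inverse-logit with clipping
#'
#' `clipped_logit()` maps proportions in \[0, 1\] to the log-odds scale after
#' clipping to `[eps, 1 - eps]`, the transform used for both WESI scores and
#' relative band powers before z-scoring. Values at exactly 0 or 1 are legal
#' inputs and are clipped (with a warning when `warn = TRUE`).
#'
#' @param p Numeric vector of proportions.
#' @param eps Clipping bound, default `1e-6`.
#' @param warn Emit a warning when clipping occurs.
#' @return Numeric vector on the log-odds scale.
#' @export
clipped_logit <- function(p, eps = 1e-6, warn = FALSE) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("proportions must lie in [0, 1]")
  hit <- p < eps | p > 1 - eps
  if (warn && any(hit, na.rm = TRUE)) {
    warn(sprintf("%d value(s) clipped to [%g, %g] before logit",
                 sum(hit, na.rm = TRUE), eps, 1 - eps))
  }
  qlogis(pmin(pmax(p, eps), 1 - eps))
}

# circular mean of angles in degrees, result in [0, 360)
circular_mean_deg <- function(deg) {
  if (length(deg) == 0) return(NA_real_)
  rad <- deg * pi / 180
  m <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  (m + 360) %% 360
}

# derive a reproducible child seed below 2^31 from a base seed and a tag
# (double arithmetic: products of large seeds overflow R integers)
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(i) * 12347) %% 2147483647)
}
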