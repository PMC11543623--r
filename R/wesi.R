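#' Per-segment relative band powers for WESI
#'
#' Computes relative delta/theta/alpha/beta power of every unflagged
#' 3-second segment of one channel (multitaper on the segment's 2-second
#' windows, absolute powers averaged, then normalised), with the wake/sleep
#' label implied by the stage of the epoch containing the segment (wake = 1,
#' any sleep stage = 0).
#'
#' @param record A high-pass-filtered [eeg_record()].
#' @param hypnogram A [hypnogram()].
#' @param channel Channel name.
#' @param mask Optional [reject_artifacts_rms()] mask; computed when `NULL`.
#' @return Tibble, one row per surviving segment: `segment` (0-based),
#'   `channel`, `stage`, `label`, `r_delta`, `r_theta`, `r_alpha`, `r_beta`.
#' @export
wesi_segments <- function(record, hypnogram, channel = "C3", mask = NULL) {
  if (is.null(mask)) mask <- reject_artifacts_rms(record)
  mask <- filter(mask, .data$channel == !!channel)
  fs <- record$fs
  sps <- SEGMENT_SEC * fs
  x <- channel_signal(record, channel)[(record$lights_off + 1):record$lights_on]
  n_seg <- length(x) %/% sps
  segs_per_epoch <- EPOCH_SEC %/% SEGMENT_SEC
  keep <- setdiff(seq_len(n_seg) - 1L, mask$segment[mask$flagged])
  keep <- keep[keep %/% segs_per_epoch < n_epochs(hypnogram)]
  purrr::map_dfr(keep, function(s) {
    seg <- x[(s * sps + 1):((s + 1) * sps)]
    bp <- multitaper_bandpowers(seg, fs)
    ab <- colMeans(bp[, c("delta", "theta", "alpha", "beta")])
    r <- relative_power(ab)
    stage <- as.character(hypnogram$stage[s %/% segs_per_epoch + 1])
    tibble(segment = s, channel = channel, stage = stage,
           label = as.integer(stage == "W"),
           r_delta = r[["delta"]], r_theta = r[["theta"]],
           r_alpha = r[["alpha"]], r_beta = r[["beta"]])
  })
}

wesi_feature_names <- function() c("delta", "theta", "alpha", "beta")

#' Transform relative powers into WESI model features
#'
#' Logit-transforms each relative band power (clipped to
#' `[eps, 1 - eps]`), then z-scores each of the four features. In training
#' mode (`train_stats = NULL`) the z-score statistics are estimated from the
#' input and attached; in scoring mode they must come from the training set.
#'
#' @param segments Tibble with columns `r_delta`, `r_theta`, `r_alpha`,
#'   `r_beta` (values strictly inside (0, 1); boundary values are clipped).
#' @param train_stats `NULL`, or a list with `mean` and `sd` (each a named
#'   4-vector) from a previous training call.
#' @param eps Clipping bound for the logit, default `1e-6`.
#' @return Tibble with columns `x_delta` .. `x_beta` plus any input label
#'   columns; training statistics in `attr(, "train_stats")`.
#' @export
build_wesi_features <- function(segments, train_stats = NULL, eps = 1e-6) {
  rcols <- paste0("r_", wesi_feature_names())
  L <- vapply(rcols, function(cl) clipped_logit(segments[[cl]], eps),
              numeric(nrow(segments)))
  L <- matrix(L, nrow = nrow(segments),
              dimnames = list(NULL, wesi_feature_names()))
  if (is.null(train_stats)) {
    mu <- colMeans(L)
    sdv <- apply(L, 2, stats::sd)
    if (any(!is.finite(sdv)) || any(sdv == 0)) {
      abort("degenerate training set: a feature has zero variance")
    }
    train_stats <- list(mean = mu, sd = sdv)
  }
  Z <- sweep(sweep(L, 2, train_stats$mean), 2, train_stats$sd, "/")
  out <- segments
  for (j in seq_along(wesi_feature_names())) {
    out[[paste0("x_", wesi_feature_names()[j])]] <- unname(Z[, j])
  }
  attr(out, "train_stats") <- train_stats
  out
}

rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train the wake EEG similarity index
#'
#' Fits a logistic classifier mapping the four transformed spectral features
#' of each 3-second segment to a wake-likeness score in \[0, 1\]. Segments
#' are randomly split 80/20 into training and test sets; z-score statistics
#' are frozen from the training split and held-out AUC/accuracy reported.
#'
#' @param segments Labelled segment tibble (columns `r_delta` .. `r_beta`,
#'   `label` in 0/1) from [wesi_segments()] or the synthetic generator.
#' @param split Training fraction, default 0.8.
#' @param seed Integer seed for the split.
#' @param eps Logit clipping bound.
#' @return Object of class `wesi_model`: coefficients, training statistics,
#'   split seed and held-out performance.
#' @export
train_wesi <- function(segments, split = 0.8, seed = 1L, eps = 1e-6) {
  if (length(unique(segments$label)) < 2) {
    abort("training needs both wake and sleep segments")
  }
  set.seed(as.integer(seed))
  n <- nrow(segments)
  idx_train <- sort(sample.int(n, round(split * n)))
  tr <- segments[idx_train, ]
  te <- segments[-idx_train, ]
  if (length(unique(tr$label)) < 2) {
    abort("training split contains a single class; adjust split or data")
  }
  ftr <- build_wesi_features(tr, NULL, eps)
  stats_ <- attr(ftr, "train_stats")
  xcols <- paste0("x_", wesi_feature_names())
  # perfect separation is a legitimate outcome on synthetic clouds; the
  # saturated fit still yields valid 0/1-saturating scores
  fit <- suppressWarnings(
    glm(as.formula(paste("label ~", paste(xcols, collapse = "+"))),
        data = ftr, family = binomial()))
  fte <- build_wesi_features(te, stats_, eps)
  p_te <- predict(fit, newdata = fte, type = "response")
  model <- structure(list(
    coef = coef(fit),
    train_stats = stats_,
    eps = eps,
    split = split,
    seed = as.integer(seed),
    n_train = nrow(tr), n_test = nrow(te),
    test_auc = rank_auc(p_te, te$label),
    test_accuracy = mean((p_te > 0.5) == (te$label == 1)),
    fingerprint = stats_fingerprint(stats_)
  ), class = "wesi_model")
  model
}

stats_fingerprint <- function(stats_) {
  paste(signif(c(stats_$mean, stats_$sd), 10), collapse = ",")
}

#' @exportS3Method base::print
print.wesi_model <- function(x, ...) {
  cat(sprintf(
    "<wesi_model> logistic on 4 logit z-scored band powers\n  n_train=%d n_test=%d  held-out AUC=%.3f acc=%.3f\n",
    x$n_train, x$n_test, x$test_auc, x$test_accuracy))
  invisible(x)
}

#' @export
tidy.wesi_model <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @export
glance.wesi_model <- function(x, ...) {
  tibble(n_train = x$n_train, n_test = x$n_test, test_auc = x$test_auc,
         test_accuracy = x$test_accuracy, split = x$split, seed = x$seed)
}

#' Score segments with a trained WESI model
#'
#' Applies the logistic model to new segments, building features with the
#' model's frozen training statistics. Pre-built feature tibbles are
#' accepted only if their training-statistics fingerprint matches the
#' model's.
#'
#' @param model A [train_wesi()] model.
#' @param segments Segment tibble with `r_*` columns (features are built
#'   internally), or a [build_wesi_features()] result.
#' @return `segments` with an added `wesi` column of scores in \[0, 1\].
#' @export
score_wesi <- function(model, segments) {
  xcols <- paste0("x_", wesi_feature_names())
  if (all(xcols %in% names(segments))) {
    st <- attr(segments, "train_stats")
    if (is.null(st) || stats_fingerprint(st) != model$fingerprint) {
      abort("features were built with different normalization statistics")
    }
    f <- segments
  } else {
    f <- build_wesi_features(segments, model$train_stats, model$eps)
  }
  eta <- model$coef[1] +
    as.matrix(f[, xcols]) %*% model$coef[xcols]
  mutate(segments, wesi = as.numeric(plogis(eta)))
}

#' Aggregate WESI scores to a per-stage feature
#'
#' Stage-level WESI is the mean of logit-transformed segment scores (the
#' analysis scale of the statistical layer); the linear-scale summary is the
#' inverse-logit of that mean, which deliberately differs from the
#' arithmetic mean of raw scores.
#'
#' @param scored Tibble from [score_wesi()] with columns `stage` and `wesi`.
#' @param eps Clipping bound for the logit of scores.
#' @return Tibble, one row per stage present: `stage`, `n_segments`,
#'   `wesi_logit_mean`, `wesi_linear` (= `plogis(wesi_logit_mean)`).
#' @export
aggregate_wesi <- function(scored, eps = 1e-6) {
  out <- summarise(group_by(scored, .data$stage),
                   n_segments = dplyr::n(),
                   wesi_logit_mean = mean(clipped_logit(.data$wesi, eps)),
                   .groups = "drop")
  mutate(out, wesi_linear = plogis(.data$wesi_logit_mean))
}

#' Serialize a WESI model to structured text
#'
#' @param model A `wesi_model`.
#' @param path Output path (YAML).
#' @return `path` invisibly; `read_wesi_model()` returns the model.
#' @export
write_wesi_model <- function(model, path) {
  yaml::write_yaml(list(
    class = "wesi_model",
    coef = as.list(model$coef),
    train_mean = as.list(model$train_stats$mean),
    train_sd = as.list(model$train_stats$sd),
    eps = model$eps, split = model$split, seed = model$seed,
    n_train = model$n_train, n_test = model$n_test,
    test_auc = model$test_auc, test_accuracy = model$test_accuracy
  ), path, precision = 15L)
  invisible(path)
}

#' @rdname write_wesi_model
#' @export
read_wesi_model <- function(path) {
  y <- yaml::read_yaml(path)
  stats_ <- list(mean = unlist(y$train_mean), sd = unlist(y$train_sd))
  structure(list(
    coef = unlist(y$coef), train_stats = stats_, eps = y$eps,
    split = y$split, seed = y$seed, n_train = y$n_train, n_test = y$n_test,
    test_auc = y$test_auc, test_accuracy = y$test_accuracy,
    fingerprint = stats_fingerprint(stats_)
  ), class = "wesi_model")
}
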