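feature_family <- function(feature) {
  dplyr::case_when(
    grepl("^wesi", feature) ~ "WESI",
    grepl("^spindle", feature) ~ "spindle",
    TRUE ~ "spectral"
  )
}

default_config <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    cohort = list(n_per_arm = list(placebo = 30, `25` = 30, `50` = 30),
                  n_sites = 6),
    features = NULL,                     # NULL -> feature_spec_default()
    effects = NULL,                      # list of {feature, arm, month, delta}
    transitions = list(enabled = TRUE, n_epochs = 240,
                       deltas = NULL,    # list of {treatment, month, from, to, delta}
                       cells = list(c("W", "W"), c("W", "N1"), c("N1", "N2"))),
    signal_tier = list(enabled = FALSE, n_epochs = 40, fs = 128),
    contrast = list(arm = "50", month = 3)
  )
}

validate_config <- function(config) {
  check <- function(cfg, ref, path = "") {
    bad <- setdiff(names(cfg), names(ref))
    if (length(bad) > 0) {
      abort(sprintf("unknown config key(s)%s: %s",
                    if (nzchar(path)) paste0(" under ", path) else "",
                    paste(bad, collapse = ", ")))
    }
    for (k in intersect(names(cfg), names(ref))) {
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) &&
          k %in% c("cohort", "transitions", "signal_tier", "contrast")) {
        if (!is.list(cfg[[k]])) abort(sprintf("config key %s must be a map", k))
        check(cfg[[k]], ref[[k]], k)
      }
    }
  }
  check(config, default_config())
  invisible(config)
}

#' Read a pipeline run configuration
#'
#' Loads a YAML configuration, validates it against the known schema
#' (unknown keys are rejected, not ignored), and merges it over the package
#' defaults.
#'
#' @param path YAML file path, or a named list already in config form.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  validate_config(cfg)
  modifyList(default_config(), cfg)
}

baseline_transition_matrix <- function() {
  P <- matrix(c(
    0.880, 0.070, 0.020, 0.005, 0.025,   # from W
    0.250, 0.350, 0.350, 0.010, 0.040,   # from N1
    0.040, 0.050, 0.840, 0.040, 0.030,   # from N2
    0.020, 0.010, 0.120, 0.840, 0.010,   # from N3
    0.040, 0.040, 0.050, 0.005, 0.865    # from REM
  ), nrow = 5, byrow = TRUE,
  dimnames = list(from = sleep_stages(), to = sleep_stages()))
  P
}

#' Run the end-to-end analysis pipeline on a simulated cohort
#'
#' Orchestrates simulate -> features -> statistics: a feature-tier cohort is
#' generated (with any configured injected effects), each feature gets the
#' null/main mixed-model pair, treatment contrast and family-wise FDR; a
#' transition-tier cohort is simulated and each configured transition cell
#' gets prevalence-based model selection, a hurdle or GLMM fit, and the
#' empirical placebo-corrected difference-in-differences. When the signal
#' tier is enabled, a short synthetic recording additionally exercises
#' preprocessing, spectral features, spindle detection and WESI
#' training/scoring end-to-end.
#'
#' @param config A config list or YAML path (see [read_run_config()]).
#' @return Object of class `somnarch_run`: `manifest`, `feature_results`,
#'   `contrasts`, `transition_results`, `signal_tier` and `config`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_run_config(config)
  seed <- as.integer(cfg$seed)
  features <- cfg$features %||% feature_spec_default()
  effects <- if (!is.null(cfg$effects)) {
    bind_rows(lapply(cfg$effects, function(e) {
      effect_spec(e$feature, e$arm, e$month, e$delta)
    }))
  } else NULL

  design <- cohort_design(
    n_per_arm = unlist(cfg$cohort$n_per_arm),
    n_sites = cfg$cohort$n_sites, seed = seed)
  cohort <- simulate_feature_cohort(design, features, effects)

  arm <- cfg$contrast$arm
  month <- cfg$contrast$month
  fits <- lapply(features$feature, function(f) {
    fit_null_and_main(filter(cohort, .data$feature == f),
                      feature = f, family = feature_family(f))
  })
  contrasts <- bind_rows(lapply(fits, treatment_contrast, arm = arm,
                                month = month))
  feature_results <- bind_rows(lapply(fits, glance))
  feature_results <- left_join(
    feature_results,
    select(contrasts, "feature", "estimate", "conf.low", "conf.high",
           contrast_p = "p.value"),
    by = "feature")
  feature_results <- fdr_correct(feature_results)

  transition_results <- NULL
  if (isTRUE(cfg$transitions$enabled)) {
    tdeltas <- if (!is.null(cfg$transitions$deltas)) {
      bind_rows(lapply(cfg$transitions$deltas, as_tibble))
    } else NULL
    tco <- simulate_transition_cohort(
      design, baseline_transition_matrix(), tdeltas,
      n_epochs = cfg$transitions$n_epochs, seed = child_seed(seed, 7L))
    probs <- cohort_transition_probabilities(tco)
    counts <- purrr::imap_dfr(tco$hypnograms, function(h, i) {
      cm <- transition_counts(h)
      mutate(tidy_transitions(cm),
             recording_id = tco$design$recording_id[[as.integer(i)]],
             opportunities = n_epochs(h) - 1L)
    })
    counts <- left_join(counts, tco$design, by = "recording_id")
    transition_results <- bind_rows(lapply(cfg$transitions$cells, function(cell) {
      cc <- filter(counts, .data$from == cell[1], .data$to == cell[2])
      prev <- mean(cc$count > 0)
      choice <- select_transition_model(prev)
      did <- transition_did(probs, cell[1], cell[2], arm, month)
      p <- NA_real_
      count_effect <- NA_real_
      if (choice == "hurdle") {
        hf <- fit_hurdle(cc)
        td <- tidy(hf)
        term <- sprintf("month%s:treatment%s", month, arm)
        row <- filter(td, .data$stage == "nonzero", .data$term == term)
        if (nrow(row) == 1) {
          p <- 2 * stats::pnorm(-abs(row$statistic))
          count_effect <- row$estimate
        }
      } else if (choice == "glmm") {
        d <- prepare_model_frame(mutate(cc, value = .data$count))
        d$count <- cc$count; d$opportunities <- cc$opportunities
        d$obs_id <- factor(seq_len(nrow(d)))
        ctrl <- lme4::glmerControl(calc.derivs = FALSE,
                                   check.conv.singular = "ignore",
                                   check.conv.grad = "ignore")
        gf <- suppressMessages(lme4::glmer(
          hurdle_formula(d, "cbind(count, opportunities - count)",
                         olre = TRUE),
          data = d, family = binomial(), control = ctrl, nAGQ = 0))
        b <- lme4::fixef(gf); V <- sqrt(diag(as.matrix(vcov(gf))))
        term <- sprintf("month%s:treatment%s", month, arm)
        if (term %in% names(b)) {
          p <- 2 * stats::pnorm(-abs(b[term] / V[term]))
          count_effect <- unname(b[term])
        }
      }
      tibble(from = cell[1], to = cell[2], prevalence = prev, model = choice,
             did = did, count_effect = count_effect, contrast_p = p)
    }))
    transition_results <- mutate(transition_results,
                                 family = "transitions",
                                 p = .data$contrast_p)
    transition_results <- fdr_correct(transition_results)
  }

  signal_tier <- NULL
  if (isTRUE(cfg$signal_tier$enabled)) {
    set.seed(child_seed(seed, 13L))
    st <- sample(c("W", "N1", "N2", "N3", "REM"), cfg$signal_tier$n_epochs,
                 replace = TRUE, prob = c(0.3, 0.1, 0.35, 0.1, 0.15))
    h <- hypnogram(st)
    rec <- highpass(synthesize_eeg(h, fs = cfg$signal_tier$fs,
                                   seed = child_seed(seed, 17L)))
    spec <- spectral_features(rec, h)
    prep <- prepare_spindle_signal(rec, h)
    sp <- if (length(prep$n2_kept) > 0) detect_spindles(prep) else NULL
    segs <- wesi_segments(rec, h)
    model <- if (length(unique(segs$label)) == 2)
      train_wesi(segs, seed = child_seed(seed, 19L)) else NULL
    wesi_stage <- if (!is.null(model))
      aggregate_wesi(score_wesi(model, segs)) else NULL
    signal_tier <- list(spectral = spec, spindles = sp, wesi_model = model,
                        wesi_stage = wesi_stage)
  }

  fit1 <- fits[[1]]
  run <- structure(list(
    manifest = list(package_version = as.character(utils::packageVersion("somnarch")),
                    seed = seed, config_hash = rlang::hash(cfg),
                    formula_null = deparse1(fit1$formulas$null),
                    formula_main = deparse1(fit1$formulas$main),
                    site_intercept_dropped = vapply(fits, function(f)
                      f$site_dropped, TRUE),
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    feature_results = feature_results,
    contrasts = contrasts,
    transition_results = transition_results,
    signal_tier = signal_tier,
    config = cfg
  ), class = "somnarch_run")

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(feature_results,
                     file.path(cfg$output_dir, "feature_results.csv"),
                     row.names = FALSE)
    if (!is.null(transition_results)) {
      utils::write.csv(transition_results,
                       file.path(cfg$output_dir, "transition_results.csv"),
                       row.names = FALSE)
    }
    yaml::write_yaml(run$manifest, file.path(cfg$output_dir, "manifest.yaml"))
    yaml::write_yaml(cfg, file.path(cfg$output_dir, "config.yaml"))
  }
  run
}

#' @exportS3Method base::print
print.somnarch_run <- function(x, ...) {
  cat(sprintf("<somnarch_run> seed=%d hash=%s\n", x$manifest$seed,
              x$manifest$config_hash))
  cat(sprintf("  %d feature fits, %s transition cells\n",
              nrow(x$feature_results),
              if (is.null(x$transition_results)) "no" else
                nrow(x$transition_results)))
  invisible(x)
}

#' Human-readable summary of a pipeline run
#'
#' Formats per-family tables of placebo-corrected contrasts with CIs and
#' significance flags, plus the transition grid with direction annotations.
#' Sections whose inputs were not computed render an explicit
#' "not computed" marker rather than being dropped.
#'
#' @param run A [run_pipeline()] result.
#' @return Character vector of report lines, invisibly; also printed.
#' @export
make_report <- function(run) {
  lines <- c(sprintf("somnarch run %s (seed %d)", run$manifest$config_hash,
                     run$manifest$seed), "")
  for (fam in c("spectral", "spindle", "WESI")) {
    fr <- filter(run$feature_results, .data$family == fam)
    lines <- c(lines, sprintf("== %s features ==", fam))
    if (nrow(fr) == 0) {
      lines <- c(lines, "  [not computed]")
    } else {
      lines <- c(lines, sprintf(
        "  %-18s %8.3f [%7.3f, %7.3f]  q=%.3f %s",
        fr$feature, fr$estimate, fr$conf.low, fr$conf.high, fr$q,
        ifelse(fr$significant, "*", "")))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "== transitions ==")
  tr <- run$transition_results
  if (is.null(tr)) {
    lines <- c(lines, "  [not computed]")
  } else {
    # direction annotation follows the modelled count effect (what the
    # p-value tests), not the descriptive probability DiD
    lines <- c(lines, sprintf(
      "  %3s -> %-3s  did=%+.4f (%s) %s",
      tr$from, tr$to, tr$did, tr$model,
      ifelse(!is.na(tr$significant) & tr$significant,
             ifelse(tr$count_effect > 0, "count increase*",
                    "count decrease*"), "")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
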