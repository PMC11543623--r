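#' Cohort design for synthetic trials
#'
#' Describes the observational structure of a pooled two-study, three-arm,
#' three-visit, two-night PSG trial: subjects per arm, sites, visit months,
#' and subject demographics. Baseline (month 0) precedes treatment; visits at
#' months 1 and 3 are on treatment. Placebo and 25 mg subjects are split
#' across the two study ids; the 50 mg arm belongs to the first study only,
#' mirroring the pooled design the statistical layer expects.
#'
#' @param n_per_arm Named integer vector of subjects per arm, names among
#'   `c("placebo", "25", "50")`.
#' @param n_sites Number of recording sites.
#' @param visits Visit months, default `c(0, 1, 3)`.
#' @param nights_per_visit Consecutive PSG nights per visit (fixed at 2).
#' @param age_mean,age_sd Age distribution (years), defaults 55 and 15.
#' @param sex_ratio Proportion female, default 0.67; sex is coded +1 female,
#'   -1 male.
#' @param seed Integer seed used for demographics and site assignment.
#' @return Object of class `cohort_design`.
#' @export
#' @examples
#' d <- cohort_design(c(placebo = 20, `50` = 10), n_sites = 4, seed = 1)
#' nrow(cohort_rows(d))
cohort_design <- function(n_per_arm = c(placebo = 586, `25` = 584, `50` = 296),
                          n_sites = 50, visits = c(0, 1, 3),
                          nights_per_visit = 2, age_mean = 55, age_sd = 15,
                          sex_ratio = 0.67, seed = 1L) {
  arms <- names(n_per_arm)
  if (is.null(arms) || !all(arms %in% c("placebo", "25", "50"))) {
    abort("n_per_arm must be named with arms among placebo, 25, 50")
  }
  if (nights_per_visit != 2) abort("nights_per_visit is fixed at 2")
  if (!all(visits %in% c(0, 1, 3))) abort("visits must be among 0, 1, 3")
  if (age_sd < 0) abort("age_sd must be >= 0")
  structure(list(n_per_arm = n_per_arm, n_sites = as.integer(n_sites),
                 visits = sort(visits), nights_per_visit = 2L,
                 age_mean = age_mean, age_sd = age_sd,
                 sex_ratio = sex_ratio, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Expand a cohort design into observation rows
#'
#' @param design A [cohort_design()].
#' @return Tibble, one row per subject x visit x night, with columns
#'   `recording_id`, `study_id`, `subject_id`, `site_id`, `treatment`,
#'   `month`, `night`, `age_centered` (years - 50) and `sex` (+1/-1).
#' @export
cohort_rows <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(child_seed(design$seed, 991L))
  subj <- purrr::imap_dfr(as.list(design$n_per_arm), function(n, arm) {
    tibble(
      treatment = arm,
      subject_idx = seq_len(n),
      # placebo and 25 mg pooled across both studies; 50 mg in study 1 only
      study_id = if (arm == "50") "S1" else c("S1", "S2")[1 + seq_len(n) %% 2]
    )
  })
  subj <- mutate(subj,
    subject_id = sprintf("%s_%03d_%s", .data$treatment, .data$subject_idx,
                         .data$study_id),
    site_id = sprintf("site%02d", sample.int(design$n_sites, nrow(subj),
                                             replace = TRUE)),
    age_centered = round(rnorm(nrow(subj), design$age_mean, design$age_sd)) - 50,
    sex = ifelse(runif(nrow(subj)) < design$sex_ratio, 1, -1)
  )
  grid <- tidyr::expand_grid(subject_id = subj$subject_id,
                             month = design$visits,
                             night = seq_len(design$nights_per_visit))
  out <- left_join(grid, select(subj, -"subject_idx"), by = "subject_id")
  out <- mutate(out,
    recording_id = sprintf("%s_m%d_n%d", .data$subject_id, .data$month,
                           .data$night)
  )
  select(out, "recording_id", "study_id", "subject_id", "site_id",
         "treatment", "month", "night", "age_centered", "sex")
}

#' Default feature specification for the feature-tier generator
#'
#' One row per analysis feature with its grand mean, per-visit drift, and
#' variance components on the analysis scale (percentage points of relative
#' power for spectral features, logit units for WESI). Means reflect typical
#' insomnia-cohort wake/N1 spectral profiles; variance components are sized
#' to the night-to-night and between-subject variability of stage-averaged
#' features (see the methods vignette).
#'
#' @return Tibble with columns `feature`, `grand_mean`, `drift_m1`,
#'   `drift_m3`, `subject_sd`, `site_sd`, `residual_sd`, `night_effect`.
#' @export
feature_spec_default <- function() {
  tibble::tribble(
    ~feature,            ~grand_mean, ~drift_m1, ~drift_m3, ~subject_sd, ~site_sd, ~residual_sd, ~night_effect,
    "wake_rel_delta",         35,        0.3,       0.5,        5,          1,         3,            0.2,
    "wake_rel_alpha",         25,       -0.2,      -0.3,        4,          1,         2.5,          0.1,
    "wake_rel_beta",          20,        0,         0,          3,          1,         2,            0.1,
    "n1_rel_beta",            12,        0,         0,          2,          0.5,       1.5,          0.1,
    "spindle_density",         2.5,      0,         0,          0.8,        0.1,       0.4,          0.05,
    "spindle_dispersion",      1.2,      0,         0,          0.3,        0.05,      0.2,          0.02,
    "wesi_wake_logit",         1.386,    0,         0,          0.5,        0.1,       0.3,          0.02
  )
}

#' Treatment effect specification
#'
#' Encodes injected placebo-corrected changes on the analysis scale: signed
#' deltas per feature, arm and post-baseline month. Placebo deltas are 0 by
#' construction and must not be supplied; baseline effects are an error.
#'
#' @param feature Feature name.
#' @param arm `"25"` or `"50"`.
#' @param month 1 or 3.
#' @param delta Signed change on the analysis scale.
#' @return Tibble with one row per (feature, arm, month).
#' @export
effect_spec <- function(feature, arm, month, delta) {
  out <- tibble(feature = feature, treatment = as.character(arm),
                month = month, delta = delta)
  if (any(out$treatment == "placebo")) {
    abort("placebo deltas are 0 by construction; do not specify them")
  }
  if (!all(out$month %in% c(1, 3))) {
    abort("effects exist only at months 1 and 3 (baseline precedes treatment)")
  }
  out
}

#' Simulate a feature-tier cohort table
#'
#' Generates one analysis observation per subject x visit x night x feature:
#' value = grand mean + visit drift + night effect + subject intercept +
#' site intercept + injected placebo-corrected delta (treated arms, months
#' 1/3) + residual noise. Effects are injected directly on the analysis
#' scale so recovery by the mixed-model layer can be checked against exact
#' ground truth. With all variance components zero the generator is exactly
#' deterministic.
#'
#' @param design A [cohort_design()].
#' @param features Feature specification tibble (see
#'   [feature_spec_default()]); may be a subset of rows.
#' @param effects Effect tibble from [effect_spec()], or `NULL` for a null
#'   cohort.
#' @return Tibble of class `feature_cohort`: the design columns plus
#'   `feature` and `value`; ground truth (`features`, `effects`) kept in
#'   attributes `truth`.
#' @export
simulate_feature_cohort <- function(design, features = feature_spec_default(),
                                    effects = NULL) {
  rows <- cohort_rows(design)
  if (!is.null(effects)) {
    bad <- setdiff(effects$feature, features$feature)
    if (length(bad) > 0) {
      abort(sprintf("effects reference unknown feature(s): %s",
                    paste(bad, collapse = ", ")))
    }
    if (any(effects$month == 0)) {
      abort("effects cannot be injected at baseline (month 0)")
    }
  }
  subjects <- unique(rows$subject_id)
  sites <- unique(rows$site_id)
  out <- purrr::pmap_dfr(features, function(feature, grand_mean, drift_m1,
                                            drift_m3, subject_sd, site_sd,
                                            residual_sd, night_effect) {
    set.seed(child_seed(design$seed, which(features$feature == feature)))
    b_subj <- setNames(rnorm(length(subjects), 0, subject_sd), subjects)
    b_site <- setNames(rnorm(length(sites), 0, site_sd), sites)
    drift <- c(`0` = 0, `1` = drift_m1, `3` = drift_m3)
    val <- grand_mean +
      drift[as.character(rows$month)] +
      night_effect * (rows$night == 2) +
      b_subj[rows$subject_id] +
      b_site[rows$site_id] +
      rnorm(nrow(rows), 0, residual_sd)
    d <- rep(0, nrow(rows))
    if (!is.null(effects)) {
      ef <- filter(effects, .data$feature == !!feature)
      for (i in seq_len(nrow(ef))) {
        hit <- rows$treatment == ef$treatment[i] & rows$month == ef$month[i]
        d[hit] <- d[hit] + ef$delta[i]
      }
    }
    mutate(rows, feature = feature, value = unname(val) + d)
  })
  attr(out, "truth") <- list(features = features, effects = effects)
  class(out) <- c("feature_cohort", class(out))
  out
}
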