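# prepare factors shared by all model fits; factors with a single observed
# level are dropped from the fixed-effect structure by the formula builder
prepare_model_frame <- function(rows) {
  d <- as_tibble(rows)
  need <- c("subject_id", "site_id", "treatment", "month", "night",
            "age_centered", "sex", "value")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    abort(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  }
  d$treatment <- factor(as.character(d$treatment),
                        levels = intersect(c("placebo", "25", "50"),
                                           unique(as.character(d$treatment))))
  d$month <- factor(d$month, levels = sort(unique(d$month)))
  d$night <- factor(d$night)
  if ("study_id" %in% names(d)) d$study_id <- factor(d$study_id)
  d
}

build_formulas <- function(d, random_site = TRUE) {
  covars <- c("age_centered", "sex", "month", "night")
  if ("study_id" %in% names(d) && nlevels(d$study_id) > 1) {
    covars <- c(covars, "study_id")
  }
  re <- "(1 | subject_id)"
  if (random_site) re <- paste(re, "+ (1 | site_id)")
  null_rhs <- paste(paste(covars, collapse = " * "), "+", re)
  main_rhs <- paste(paste(covars, collapse = " * "),
                    "+ month * night * treatment +", re)
  list(null = as.formula(paste("value ~", null_rhs)),
       main = as.formula(paste("value ~", main_rhs)))
}

#' Fit the null and main-effect mixed models for one feature
#'
#' Null model: full factorial of age (centred at 50), sex (+1/-1), month,
#' night and study id, with random intercepts for subject and site. Main
#' model: the null fixed effects plus month x night x treatment terms.
#' Both are fitted by maximum likelihood (so the likelihood-ratio test
#' between them is valid); a singular random-effect fit triggers a refit
#' without the site intercept, with a warning.
#'
#' @param rows Tibble of observations for a single feature, with columns
#'   `subject_id`, `site_id`, `treatment`, `month`, `night`, `age_centered`,
#'   `sex`, `value` and optionally `study_id` and `feature`.
#' @param feature Feature name recorded in the result (taken from the
#'   `feature` column when present).
#' @param family Feature family label for FDR grouping (`"spectral"`,
#'   `"spindle"`, `"WESI"`, `"transitions"`).
#' @param lrt Also fit the null model and run the likelihood-ratio test
#'   (default). With `lrt = FALSE` only the main model is fitted (for
#'   contrast-only use) and the LRT fields are `NA`.
#' @return Object of class `arousal_fit`: both fitted models, the LRT
#'   statistic/df/p, the prepared data and bookkeeping.
#' @export
fit_null_and_main <- function(rows, feature = NULL, family = "spectral",
                              lrt = TRUE) {
  d <- prepare_model_frame(rows)
  if (nlevels(d$treatment) < 2) abort("need at least two treatment arms")
  if (nlevels(d$month) < 2) abort("need baseline and at least one visit")
  feature <- feature %||% if ("feature" %in% names(rows))
    as.character(rows$feature[1]) else "feature"

  fit_pair <- function(random_site) {
    ff <- build_formulas(d, random_site)
    ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                              check.conv.singular = "ignore")
    list(
      null = if (lrt) suppressMessages(
        lme4::lmer(ff$null, data = d, REML = FALSE, control = ctrl)),
      main = suppressMessages(lme4::lmer(ff$main, data = d, REML = FALSE,
                                         control = ctrl)),
      formulas = ff, random_site = random_site
    )
  }
  fits <- fit_pair(TRUE)
  fallback <- FALSE
  if (lme4::isSingular(fits$main) ||
      (lrt && lme4::isSingular(fits$null))) {
    warn("singular random-effect fit: dropping the site intercept")
    fits <- fit_pair(FALSE)
    fallback <- TRUE
  }
  lrt_tab <- if (lrt) anova(fits$null, fits$main)
  structure(list(
    feature = feature, family = family,
    null = fits$null, main = fits$main,
    formulas = fits$formulas, site_dropped = fallback,
    lrt_stat = if (lrt) lrt_tab$Chisq[2] else NA_real_,
    lrt_df = if (lrt) lrt_tab$Df[2] else NA_integer_,
    p = if (lrt) lrt_tab$`Pr(>Chisq)`[2] else NA_real_,
    data = d
  ), class = "arousal_fit")
}

#' @exportS3Method base::print
print.arousal_fit <- function(x, ...) {
  cat(sprintf("<arousal_fit> %s (%s): LRT chi2=%.2f df=%d p=%.3g%s\n",
              x$feature, x$family, x$lrt_stat, x$lrt_df, x$p,
              if (x$site_dropped) " [site intercept dropped]" else ""))
  invisible(x)
}

#' @export
tidy.arousal_fit <- function(x, ...) {
  b <- lme4::fixef(x$main)
  se <- sqrt(diag(as.matrix(vcov(x$main))))
  tibble(term = names(b), estimate = unname(b), std.error = unname(se),
         statistic = unname(b / se))
}

#' @export
glance.arousal_fit <- function(x, ...) {
  tibble(feature = x$feature, family = x$family,
         logLik_null = as.numeric(logLik(x$null)),
         logLik_main = as.numeric(logLik(x$main)),
         lrt_stat = x$lrt_stat, lrt_df = x$lrt_df, p = x$p,
         nobs = nrow(x$data), site_dropped = x$site_dropped)
}

# average fixed-effect design row for one treatment x month cell:
# age at 0 (i.e. 50 years), sex at 0 (sex is +1/-1 coded, so 0 is the
# midpoint), nights and studies averaged
cell_design_row <- function(fit, arm, month) {
  d <- fit$data
  tt <- stats::delete.response(stats::terms(fit$main, fixed.only = TRUE))
  grid <- tidyr::expand_grid(
    night = factor(levels(d$night), levels(d$night)),
    study_id = if ("study_id" %in% names(d) && is.factor(d$study_id))
      factor(levels(d$study_id), levels(d$study_id)) else NA
  )
  nd <- mutate(grid,
               treatment = factor(arm, levels(d$treatment)),
               month = factor(as.character(month), levels(d$month)),
               age_centered = 0, sex = 0)
  if (!"study_id" %in% names(d) || !is.factor(d$study_id)) nd$study_id <- NULL
  X <- model.matrix(tt, nd)
  colMeans(X)
}

#' Placebo-corrected treatment contrast with Wald confidence interval
#'
#' Computes the placebo-corrected change from baseline,
#' `(arm at month m - arm at baseline) - (reference at month m - reference
#' at baseline)`, or the plain change from baseline when
#' `reference = NULL`, as a linear combination of the main model's fixed
#' effects, with delta-method (Wald) standard error and 95% CI.
#'
#' @param fit An [fit_null_and_main()] result.
#' @param arm Treatment arm (`"25"` or `"50"`).
#' @param month Post-baseline month (1 or 3).
#' @param reference Reference arm, default `"placebo"`; `NULL` for a
#'   change-from-baseline contrast within `arm`.
#' @param level Confidence level, default 0.95.
#' @return One-row tibble: `feature`, `arm`, `month`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`, `p.value`.
#' @export
treatment_contrast <- function(fit, arm, month, reference = "placebo",
                               level = 0.95) {
  d <- fit$data
  if (!arm %in% levels(d$treatment)) {
    abort(sprintf("arm %s absent from the data", arm))
  }
  cv <- cell_design_row(fit, arm, month) - cell_design_row(fit, arm, 0)
  if (!is.null(reference)) {
    if (!reference %in% levels(d$treatment)) {
      abort(sprintf("reference arm %s absent from the data", reference))
    }
    cv <- cv - (cell_design_row(fit, reference, month) -
                  cell_design_row(fit, reference, 0))
  }
  b <- lme4::fixef(fit$main)
  V <- as.matrix(vcov(fit$main))
  cv <- cv[names(b)]
  est <- sum(cv * b)
  se <- sqrt(drop(t(cv) %*% V %*% cv))
  z <- qnorm(1 - (1 - level) / 2)
  tibble(feature = fit$feature, arm = arm, month = month,
         estimate = est, std.error = se,
         conf.low = est - z * se, conf.high = est + z * se,
         p.value = 2 * stats::pnorm(-abs(est / se)))
}

#' Model-implied mean for one treatment x month cell
#'
#' Fixed-effect prediction for a treatment arm at a visit month, at age 50,
#' sex midpoint, averaged over nights and studies — the cell means whose
#' differences [treatment_contrast()] reports. For WESI fits this is the
#' logit-scale mean handed to [wesi_linear_scale()].
#'
#' @param fit An [fit_null_and_main()] result.
#' @param arm Treatment arm label.
#' @param month Visit month.
#' @return One-row tibble: `arm`, `month`, `estimate`, `std.error`.
#' @export
cell_mean <- function(fit, arm, month) {
  cv <- cell_design_row(fit, arm, month)
  b <- lme4::fixef(fit$main)
  V <- as.matrix(vcov(fit$main))
  cv <- cv[names(b)]
  tibble(arm = arm, month = month, estimate = sum(cv * b),
         std.error = sqrt(drop(t(cv) %*% V %*% cv)))
}
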