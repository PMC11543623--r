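#' Choose how to model one transition's counts
#'
#' Transitions present in fewer than 1.5% of recordings are not modelled at
#' all; those present in 1.5% to 98.5% of recordings get a two-stage hurdle
#' model; near-ubiquitous transitions (> 98.5%) get an ordinary generalized
#' mixed model.
#'
#' @param prevalence Fraction of recordings containing the transition, in
#'   \[0, 1\].
#' @param lo,hi Prevalence bounds, defaults 0.015 and 0.985.
#' @return `"excluded"`, `"hurdle"` or `"glmm"`.
#' @export
select_transition_model <- function(prevalence, lo = 0.015, hi = 0.985) {
  stopifnot(prevalence >= 0, prevalence <= 1)
  if (prevalence < lo) "excluded"
  else if (prevalence <= hi) "hurdle"
  else "glmm"
}

hurdle_formula <- function(d, response, random_site = TRUE, olre = FALSE) {
  covars <- c("age_centered", "sex", "month", "night")
  if ("study_id" %in% names(d) && nlevels(factor(d$study_id)) > 1) {
    covars <- c(covars, "study_id")
  }
  re <- "(1 | subject_id)"
  if (random_site) re <- paste(re, "+ (1 | site_id)")
  # observation-level intercept absorbs the extra-binomial variation of
  # Markov transition counts relative to a conditional binomial
  if (olre) re <- paste(re, "+ (1 | obs_id)")
  as.formula(paste(response, "~", paste(covars, collapse = " + "),
                   "+ month * treatment +", re))
}

#' Fit a two-stage hurdle model for one transition's counts
#'
#' Stage one models the probability that a recording contains the transition
#' zero times; stage two, conditioned on a non-zero count, models the counts
#' as successes out of the recording's transition opportunities
#' (`n_epochs - 1`). Both stages are generalized mixed models with a
#' logistic link, random intercepts for subject and site, and the shared
#' covariate structure (additive covariates with month x treatment terms;
#' the factorial used by the linear layer is reduced here to keep the
#' binomial fits identifiable on sparse counts).
#'
#' @param rows Tibble with columns `count`, `opportunities`, plus the
#'   covariate columns of [fit_null_and_main()].
#' @param random_site Include the site intercept, default `TRUE`.
#' @return Object of class `hurdle_fit` with elements `zero` (glmerMod for
#'   the zero indicator), `nonzero` (glmerMod for counts given non-zero)
#'   and `prevalence`.
#' @export
fit_hurdle <- function(rows, random_site = TRUE) {
  d <- prepare_model_frame(mutate(rows, value = .data$count))
  d$count <- rows$count
  d$opportunities <- rows$opportunities
  d$zero <- as.integer(d$count == 0)
  if (all(d$zero == 1) || all(d$zero == 0)) {
    abort(paste("all counts are zero or all non-zero:",
                "use select_transition_model first"))
  }
  ctrl <- lme4::glmerControl(calc.derivs = FALSE,
                             check.conv.singular = "ignore",
                             check.conv.grad = "ignore")
  zero_fit <- suppressMessages(lme4::glmer(
    hurdle_formula(d, "zero", random_site), data = d,
    family = binomial(), control = ctrl, nAGQ = 0))
  dn <- filter(d, .data$count > 0)
  dn$obs_id <- factor(seq_len(nrow(dn)))
  nonzero_fit <- suppressMessages(lme4::glmer(
    hurdle_formula(dn, "cbind(count, opportunities - count)", random_site,
                   olre = TRUE),
    data = dn, family = binomial(), control = ctrl, nAGQ = 0))
  structure(list(zero = zero_fit, nonzero = nonzero_fit,
                 prevalence = mean(d$count > 0)),
            class = "hurdle_fit")
}

#' @exportS3Method base::print
print.hurdle_fit <- function(x, ...) {
  cat(sprintf("<hurdle_fit> prevalence=%.3f; zero + nonzero logistic stages\n",
              x$prevalence))
  invisible(x)
}

#' @export
tidy.hurdle_fit <- function(x, ...) {
  stage_tidy <- function(fit, stage) {
    b <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    tibble(stage = stage, term = names(b), estimate = unname(b),
           std.error = unname(se), statistic = unname(b / se))
  }
  bind_rows(stage_tidy(x$zero, "zero"), stage_tidy(x$nonzero, "nonzero"))
}

#' Benjamini-Hochberg correction within feature families
#'
#' Applies BH FDR correction to likelihood-ratio p-values separately within
#' each feature family (spectral, spindle, WESI, transitions). A feature is
#' flagged significant under the dual criterion: family-corrected `q < 0.05`
#' and its treatment contrast `p < .05` (when a `contrast_p` column is
#' present).
#'
#' @param results Tibble with columns `family` and `p` (and optionally
#'   `contrast_p`).
#' @param alpha Significance level for the dual criterion, default 0.05.
#' @return `results` with added `q` and `significant` columns.
#' @export
fdr_correct <- function(results, alpha = 0.05) {
  if (nrow(results) == 0) {
    return(mutate(results, q = numeric(0), significant = logical(0)))
  }
  out <- mutate(group_by(results, .data$family),
                q = p.adjust(.data$p, method = "BH"))
  out <- ungroup(out)
  sig <- out$q < alpha
  if ("contrast_p" %in% names(out)) sig <- sig & out$contrast_p < alpha
  mutate(out, significant = sig)
}

#' Back-transform a logit-scale WESI estimate to the linear scale
#'
#' Maps a logit-scale mean and its standard error to the 0-1 score scale:
#' the linear mean is the inverse logit; its standard error comes from the
#' delta method with the derivative taken by central finite differences. An
#' optional parametric bootstrap (normal draws on the logit scale) validates
#' the finite-difference interval.
#'
#' @param estimate Logit-scale estimate.
#' @param std.error Logit-scale standard error.
#' @param level Confidence level, default 0.95.
#' @param h Finite-difference step, default `1e-5`.
#' @param bootstrap Also compute a bootstrap CI.
#' @param n_boot Bootstrap draws, default 10000.
#' @param seed Seed for the bootstrap.
#' @return One-row tibble: `mean`, `conf.low`, `conf.high` (and
#'   `boot.low`, `boot.high` when `bootstrap = TRUE`).
#' @export
wesi_linear_scale <- function(estimate, std.error, level = 0.95, h = 1e-5,
                              bootstrap = FALSE, n_boot = 10000, seed = 1L) {
  m <- plogis(estimate)
  deriv <- (plogis(estimate + h) - plogis(estimate - h)) / (2 * h)
  se_lin <- deriv * std.error
  z <- qnorm(1 - (1 - level) / 2)
  out <- tibble(mean = m, conf.low = m - z * se_lin,
                conf.high = m + z * se_lin)
  if (bootstrap) {
    set.seed(as.integer(seed))
    draws <- plogis(rnorm(n_boot, estimate, std.error))
    qs <- quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2))
    out$boot.low <- qs[[1]]
    out$boot.high <- qs[[2]]
  }
  out
}
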