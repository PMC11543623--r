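#' Transition-change grid plot
#'
#' Tile grid of placebo-corrected transition-probability changes (from-stage
#' rows, to-stage columns), with significant cells outlined, in the style of
#' a sleep-wake transition summary figure.
#'
#' @param transition_results Tibble with columns `from`, `to`, `did` and
#'   optionally `significant` (from [run_pipeline()] or built manually).
#' @return A ggplot object.
#' @export
plot_transition_grid <- function(transition_results) {
  d <- mutate(transition_results,
              from = factor(.data$from, rev(sleep_stages())),
              to = factor(.data$to, sleep_stages()),
              sig = if ("significant" %in% names(transition_results))
                !is.na(.data$significant) & .data$significant else FALSE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$to, y = .data$from)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$did), colour = "grey60") +
    ggplot2::geom_tile(data = filter(d, .data$sig), fill = NA,
                       colour = "black", linewidth = 1) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%+.3f", .data$did))) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "indianred", midpoint = 0,
                                  name = "Δ probability") +
    ggplot2::labs(x = "to stage", y = "from stage",
                  title = "Placebo-corrected transition-probability change") +
    ggplot2::theme_minimal()
}

#' Forest plot of treatment contrasts
#'
#' @param object A [run_pipeline()] result (its `feature_results` table is
#'   plotted: placebo-corrected contrasts with 95% CIs per feature).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.somnarch_run <- function(object, ...) {
  fr <- object$feature_results
  ggplot2::ggplot(fr, ggplot2::aes(x = .data$estimate, y = .data$feature,
                                   colour = .data$family)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "placebo-corrected contrast (analysis scale)",
                  y = NULL, title = "Treatment contrasts with 95% CI") +
    ggplot2::theme_minimal()
}

#' Per-stage spectral profile plot
#'
#' @param features Output of [spectral_features()].
#' @return A ggplot object (stacked relative band power per stage).
#' @export
plot_stage_spectra <- function(features) {
  d <- filter(features, is.finite(.data$rel_power))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$stage, y = .data$rel_power,
    fill = factor(.data$band, c("delta", "theta", "alpha", "beta")))) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "PuBu", name = "band") +
    ggplot2::labs(x = NULL, y = "relative power",
                  title = "Stage-wise relative band power") +
    ggplot2::theme_minimal()
}
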