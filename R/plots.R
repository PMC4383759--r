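# ggplot2 renderings of fitted decision rules and regime-value comparisons.

#' Plot a fitted decision rule
#'
#' Stage 2: recommended high-dose drug for placebo non-responders over a grid
#' of end-of-stage-1 mood elevation (SUMM1) by sedation side effect (SIDE3).
#' Stage 1: recommended first-line treatment over a grid of age by prior
#' episode type. Covariates required by non-default term sets can be fixed
#' via `at`.
#'
#' @param object A `dtr_fit`.
#' @param stage 1 or 2.
#' @param at Named list of fixed values for any further terms the model uses
#'   (defaults: published cohort means, side effects absent).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dtr_fit
#' @export
autoplot.dtr_fit <- function(object, stage = 2, at = list(), ...) {
  defaults <- list(AGE = 40.59, SUMD0 = 7.47, SUMM0 = 1.19, SUMD1 = 4.49,
                   SUMM1 = 0.95, RACE = 1, HINCOME = 0, EMPLOY = 0,
                   EDUCATE = 0, MEDINS = 1, BITYPE = 1, GENDER = "female",
                   MARSTAT = "never", PRONSET = "mixed")
  for (v in paste0("SIDE", 1:9)) defaults[[v]] <- 0
  defaults[names(at)] <- at

  if (stage == 2) {
    grid <- tidyr::expand_grid(SUMM1 = seq(0, 7, by = 0.05),
                               SIDE3 = c(0L, 1L))
    grid$Trt1 <- "PBO"
    grid$RESPONSE1 <- 0L
    for (v in setdiff(names(defaults), names(grid))) grid[[v]] <- defaults[[v]]
    grid$rec <- decide(object, grid, stage = 2)
    ggplot2::ggplot(grid, ggplot2::aes(x = .data$SUMM1,
                                       y = factor(.data$SIDE3),
                                       fill = .data$rec)) +
      ggplot2::geom_tile() +
      ggplot2::labs(x = "SUMM1 (mood elevation, end of stage 1)",
                    y = "Sedation side effect (SIDE3)",
                    fill = "Recommended",
                    title = "Second-stage rule for placebo non-responders") +
      ggplot2::theme_minimal()
  } else {
    grid <- tidyr::expand_grid(AGE = seq(18, 77, by = 0.5),
                               PRONSET = .PRONSET_LEVELS)
    for (v in setdiff(names(defaults), names(grid))) grid[[v]] <- defaults[[v]]
    grid$rec <- decide(object, grid, stage = 1)
    ggplot2::ggplot(grid, ggplot2::aes(x = .data$AGE,
                                       y = factor(.data$PRONSET,
                                                  levels = .PRONSET_LEVELS),
                                       fill = .data$rec)) +
      ggplot2::geom_tile() +
      ggplot2::labs(x = "Age (years)", y = "Prior episode",
                    fill = "Recommended",
                    title = "First-stage rule") +
      ggplot2::theme_minimal()
  }
}

#' Plot regime-value comparisons
#'
#' Dot-and-interval display of the IPWE estimates returned by
#' [compare_regimes()]; lower is better.
#'
#' @param object A `regime_values` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot regime_values
#' @export
autoplot.regime_values <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$estimate,
                               y = stats::reorder(.data$regime,
                                                  -.data$estimate))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::labs(x = "Estimated 12-week depression score (lower is better)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
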