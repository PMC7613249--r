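# Diagnostic figures: variant-level MR scatter and the statin-interaction
# plot.

#' Scatter of variant-outcome vs variant-exposure effects with MR fits
#'
#' Each point is one harmonized variant; overlaid lines show the IVW fit
#' (through the origin) and the MR-Egger fit (free intercept). A visibly
#' nonzero Egger intercept suggests directional pleiotropy.
#'
#' @param object A [harmonize()]d set.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.harmonized_set <- function(object, ...) {
  h <- object
  flip <- h$gamma < 0
  df <- tibble::tibble(gamma = ifelse(flip, -h$gamma, h$gamma),
                       Gamma = ifelse(flip, -h$Gamma, h$Gamma),
                       se_Gamma = h$se_Gamma)
  ivw <- mr_ivw(h)
  egg <- mr_egger(h)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gamma, y = .data$Gamma)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$Gamma - .data$se_Gamma,
                                        ymax = .data$Gamma + .data$se_Gamma),
                           linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_abline(intercept = 0, slope = ivw$beta,
                         colour = "#1f78b4") +
    ggplot2::geom_abline(intercept = egg$egger_intercept, slope = egg$beta,
                         colour = "#e31a1c", linetype = "dashed") +
    ggplot2::labs(x = "variant effect on exposure",
                  y = "variant effect on outcome",
                  title = "Two-sample MR: IVW (solid) and Egger (dashed)") +
    ggplot2::theme_minimal()
}

#' Forest-style plot of MR estimates
#'
#' @param object An `mr_result` tibble (possibly several stacked rows).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mr_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$beta, y = .data$method)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "causal estimate (outcome units per exposure unit)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Measured exposure against genetic score, by statin use
#'
#' Visualizes effect modification: statin users show a flatter slope of
#' measured LDL on the standardized genetic risk score.
#'
#' @param data Data frame.
#' @param measured_exposure,score,statin Column names.
#' @return A ggplot.
#' @export
plot_statin_interaction <- function(data, measured_exposure = "exposure_measured",
                                    score = "score", statin = "on_statin") {
  df <- tibble::tibble(
    score = as.numeric(scale(data[[score]])),
    exposure = as.numeric(data[[measured_exposure]]),
    statin = factor(ifelse(as.logical(data[[statin]]),
                           "statin user", "non-user"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$exposure,
                                   colour = .data$statin)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = "standardized genetic risk score",
                  y = "measured exposure",
                  colour = NULL,
                  title = "Statin use attenuates the score-exposure slope") +
    ggplot2::theme_minimal()
}
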