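#' Coefficient plot for a fitted D6SR model
#'
#' Posterior medians with 95% credible intervals for the fixed effects and
#' variance components.
#'
#' @param object A `d6sr_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.d6sr_fit <- function(object, ...) {
  sm <- tidy(object)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "posterior median (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Spaghetti plot of predicted response curves
#'
#' Posterior-median curve with individual posterior draw curves, as returned
#' by [predict_curve()].
#'
#' @param object A `d6sr_prediction`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.d6sr_prediction <- function(object, ...) {
  g <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$estimate))
  dr <- attr(object, "draws")
  if (!is.null(dr)) {
    g <- g + ggplot2::geom_line(
      data = dr, ggplot2::aes(y = .data$value, group = .data$draw),
      alpha = 0.05, colour = "steelblue")
  }
  g + ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = unique(object$covariate), y = "predicted D6SR") +
    ggplot2::theme_minimal()
}

#' Plot a joint diameter-CO2 trajectory
#'
#' Predicted D6SR along a simultaneous diameter and CO2 path, with its
#' posterior envelope and the trajectory maximum marked.
#'
#' @param object A `d6sr_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.d6sr_trajectory <- function(object, ...) {
  mx <- find_trajectory_maximum(object)
  g <- ggplot2::ggplot(object, ggplot2::aes(x = .data$diameter, y = .data$estimate))
  if (!all(is.na(object$conf.low))) {
    g <- g + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      fill = "steelblue", alpha = 0.2)
  }
  g + ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_point(data = mx, ggplot2::aes(y = .data$d6sr_max),
                        colour = "firebrick", size = 2) +
    ggplot2::labs(x = "diameter (cm)", y = "predicted D6SR") +
    ggplot2::theme_minimal()
}

#' Posterior predictive density overlay
#'
#' Kernel density of the observed D6SR values over densities of replicated
#' datasets drawn from the posterior predictive distribution — the standard
#' graphical goodness-of-fit check.
#'
#' @param fit A `d6sr_fit`.
#' @param ndraws Number of replicated datasets to draw.
#' @param seed Seed for the predictive noise.
#' @return A ggplot.
#' @export
plot_posterior_predictive <- function(fit, ndraws = 50, seed = 1L) {
  yrep <- posterior_predictive(fit, ndraws = ndraws, seed = seed)
  rep_df <- tibble::tibble(
    draw = rep(seq_len(nrow(yrep)), each = ncol(yrep)),
    d6sr = as.vector(t(yrep)))
  obs_df <- tibble::tibble(d6sr = fit$obs$d6sr)
  ggplot2::ggplot(rep_df, ggplot2::aes(x = .data$d6sr, group = .data$draw)) +
    ggplot2::geom_density(colour = "steelblue", alpha = 0.15, linewidth = 0.3) +
    ggplot2::geom_density(data = obs_df, ggplot2::aes(group = NULL),
                          colour = "black", linewidth = 1) +
    ggplot2::labs(x = "D6SR", y = "density") +
    ggplot2::theme_minimal()
}
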