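#' Plot a simulated trajectory
#'
#' State fractions over time, with the LPS level as a dashed overlay.
#'
#' @param object A `norm_trajectory` from [simulate_ode()] or
#'   [simulate_gillespie()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.norm_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("time_h", "f_negative", "f_positive", "f_nrs", "f_nrps")],
    -"time_h", names_to = "state", values_to = "fraction")
  long$state <- factor(sub("^f_", "", long$state),
                       levels = c("negative", "positive", "nrs", "nrps"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$fraction,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(
      data = tibble::tibble(time_h = object$time_h, fraction = object$lps,
                            state = "LPS"),
      linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "time (h)", y = "fraction of cells",
                  colour = NULL,
                  caption = "dashed grey: normalized LPS concentration") +
    ggplot2::theme_minimal()
}

#' Plot an ensemble summary against its mean field
#'
#' Replicate mean with a +/- 2 SE ribbon per state; if an ODE trajectory is
#' supplied it is overlaid as the mean-field reference.
#'
#' @param object A `norm_ensemble` from [simulate_ensemble()].
#' @param ode Optional `norm_trajectory` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.norm_ensemble <- function(object, ode = NULL, ...) {
  df <- tibble::as_tibble(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - 2 * .data$se,
                                      ymax = .data$mean + 2 * .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "cells (ensemble mean ± 2 SE)") +
    ggplot2::theme_minimal()
  if (!is.null(ode)) {
    long <- tidyr::pivot_longer(
      tibble::as_tibble(ode)[c("time_h", "negative", "positive", "nrs", "nrps")],
      -"time_h", names_to = "state", values_to = "mean")
    long$state <- factor(long$state, levels = levels(df$state))
    gg <- gg + ggplot2::geom_line(data = long, colour = "red", linetype = "dashed")
  }
  gg
}

#' Plot the retained parameter sets of a rejection fit
#'
#' Box-and-whisker summary of the top-k parameter values per rate, the
#' standard view of the posterior-like cloud the rejection sampler retains.
#'
#' @param object A `norm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.norm_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$samples[intersect(RATE_NAMES_FREE, names(object$samples))],
    dplyr::everything(), names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$parameter, .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "rate (per day)",
                  title = sprintf("top %d sets, %d-state model",
                                  nrow(object$samples), object$spec$n_states)) +
    ggplot2::theme_minimal()
}

#' Plot first- and total-order sensitivity indices
#'
#' Si/STi bars per parameter, faceted by model output.
#'
#' @param object A `norm_sensitivity` from [efast_analyze()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.norm_sensitivity <- function(object, ...) {
  long <- tidy.norm_sensitivity(object)
  ggplot2::ggplot(long, ggplot2::aes(.data$parameter, .data$value,
                                     fill = .data$index)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~output) +
    ggplot2::labs(x = NULL, y = "sensitivity index", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an RMSD convergence curve
#'
#' @param x A `norm_convergence` from [rmsd_convergence()].
#' @return A ggplot object.
#' @export
plot_rmsd_convergence <- function(x) {
  long <- tidyr::pivot_longer(tibble::as_tibble(x),
                              c("best_rmsd", "topk_mean_rmsd"),
                              names_to = "statistic", values_to = "rmsd")
  ggplot2::ggplot(long, ggplot2::aes(.data$n_sampled, .data$rmsd,
                                     colour = .data$statistic)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "parameter sets sampled", y = "RMSD", colour = NULL) +
    ggplot2::theme_minimal()
}
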