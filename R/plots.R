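#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated generation series against the analytic curve
#'
#' @param object A `tlox_sim` table from [simulate_population()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tlox_sim <- function(object, ...) {
  expected <- attr(object, "expected")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_line(
      ggplot2::aes(y = expected, linetype = "analytic"),
      colour = "grey40"
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$labeled_fraction, shape = "simulated"),
      size = 2
    ) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(
      x = "generation", y = "labeled fraction",
      title = "Cumulative reporter activation across divisions",
      linetype = NULL, shape = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot culture labeling kinetics over time
#'
#' @param object A `tlox_culture` table from [simulate_culture()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tlox_culture <- function(object, ...) {
  sched <- attr(object, "schedule")
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h,
                                        y = .data$labeled_fraction)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(
      x = "hours in culture", y = "labeled fraction",
      title = "Labeling kinetics in asynchronous culture"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(sched) && sched$cre_start > 0) {
    p <- p + ggplot2::geom_vline(xintercept = sched$cre_start,
                                 linetype = "dashed", colour = "grey50")
  }
  p
}

#' Plot predicted labeled fractions along a stage path
#'
#' @param object A `tlox_stage_prediction` from [predict_stage_fractions()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tlox_stage_prediction <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$stage <- factor(df$stage, levels = df$stage[order(df$order)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage,
                                   y = .data$predicted_fraction,
                                   group = .data$driver)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "predicted labeled fraction",
      title = unique(df$driver)[1]
    ) +
    ggplot2::theme_minimal()
}

#' Intensity histogram with the applied gate
#'
#' Shows the log-intensity distribution of the gated channel per group with
#' the threshold used by [gate_events()], the in-silico version of checking
#' gate placement on a FACS histogram.
#'
#' @param events An event table (from [generate_cohort()]).
#' @param gates The matching `tlox_gates` result.
#' @return A ggplot.
#' @export
plot_gating <- function(events, gates) {
  g <- gate_summary(gates)
  df <- tibble::tibble(
    group = events$group,
    log_intensity = log(events[[g$channel]])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_intensity)) +
    ggplot2::geom_histogram(bins = 80, fill = "grey70", colour = NA) +
    ggplot2::geom_vline(xintercept = g$threshold_log, colour = "red",
                        linetype = "dashed") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(
      x = sprintf("log %s", g$channel), y = "cells",
      title = sprintf("Gate at log intensity %.2f (%s policy)",
                      g$threshold_log, g$policy)
    ) +
    ggplot2::theme_minimal()
}

#' Compare analytic labeling curves across model variants
#'
#' @param k_max Largest generation to draw.
#' @param params_list Named list of [tlox_params()] objects; defaults to the
#'   maximal simplified and exact models, whose curves bracket the expected
#'   labeling (43.75% vs 29/72 after two cycles).
#' @return A ggplot.
#' @export
plot_label_curves <- function(k_max = 6, params_list = NULL) {
  if (is.null(params_list)) {
    params_list <- list(
      simplified = tlox_params("simplified", p = 0.25),
      exact = tlox_params("exact", c = 1)
    )
  }
  df <- purrr::imap_dfr(params_list, function(pp, nm) {
    out <- label_curve(k_max, pp)
    out$model <- nm
    tibble::as_tibble(out)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$fraction,
                                   colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "generation", y = "labeled fraction", colour = NULL,
                  title = "Analytic labeling curves") +
    ggplot2::theme_minimal()
}
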