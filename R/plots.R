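## ggplot2 graphics for the package's result types

#' Plot typical analyte profiles for several doses
#'
#' The classic three-panel view: typical predictions of total drug, free
#' target and total target versus time, one curve per dose.
#'
#' @param params A [tmdd_params] object.
#' @param doses_mg Doses to draw (default: the reference design's four dose
#'   levels).
#' @param times Prediction grid in days.
#' @return A ggplot object.
#' @export
plot_typical_profiles <- function(params, doses_mg = c(75, 150, 300, 375),
                                  times = seq(0, 84, by = 0.5)) {
  df <- purrr::map_dfr(doses_mg, function(d) {
    tr <- typical_prediction(params, d, times)
    dplyr::mutate(tibble::as_tibble(tr), dose_mg = d)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = factor(.data$dose_mg))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (days)", y = "concentration (ng/mL)",
                  colour = "dose (mg)") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a typical/individual trajectory
#'
#' @param object A `tmdd_trajectory` tibble.
#' @param ... Unused.
#' @return A ggplot object (one panel per analyte).
#' @export
autoplot.tmdd_trajectory <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "concentration (ng/mL)",
                  title = paste("dose", attr(object, "dose_mg"), "mg")) +
    ggplot2::theme_bw()
}

#' Autoplot a population prediction area
#'
#' @param object A `tmdd_ppa` object.
#' @param ... Unused.
#' @return A ggplot object: median free-target prediction with the 95
#'   percent prediction ribbon.
#' @export
autoplot.tmdd_ppa <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(.data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::labs(x = "time (days)", y = "free target (ng/mL)",
                  title = sprintf("95%% population prediction area, %g mg (PPA = %.1f)",
                                  attr(object, "dose_mg"), attr(object, "ppa"))) +
    ggplot2::theme_bw()
}

#' Autoplot the per-dose decision-error curve
#'
#' @param object A `tmdd_decision` object.
#' @param ... Unused.
#' @return A ggplot object: probability of an incorrect decision versus
#'   dose, with the true dose marked.
#' @export
autoplot.tmdd_decision <- function(object, ...) {
  ggplot2::ggplot(object$per_dose, ggplot2::aes(.data$dose_mg, .data$p_incorrect)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$true_dose, linetype = "dashed") +
    ggplot2::labs(x = "dose (mg)", y = "P(incorrect decision)") +
    ggplot2::theme_bw()
}

#' Autoplot a line-search criterion trace
#'
#' @param object A `tmdd_ls` object.
#' @param ... Unused.
#' @return A ggplot object: log-determinant per accepted move.
#' @export
autoplot.tmdd_ls <- function(object, ...) {
  ggplot2::ggplot(object$criterion_trace, ggplot2::aes(.data$step, .data$log_det)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "accepted move", y = "log det FIM",
                  title = paste("line search, design", object$initial_design$id)) +
    ggplot2::theme_bw()
}

#' Autoplot SSE estimate spread
#'
#' @param object A `tmdd_sse` object.
#' @param ... Unused.
#' @return A ggplot object: replicate estimates scaled by the simulation
#'   truth, one box per parameter (log scale).
#' @export
autoplot.tmdd_sse <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(ratio = .data$estimate / .data$true_value)
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter, .data$ratio)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "estimate / truth",
                  title = paste("SSE, design", object$design_id)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
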