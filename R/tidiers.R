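## broom-style tidiers for the package's result objects

#' Tidy an SSE result into long format
#'
#' @param x A `tmdd_sse` object.
#' @param ... Unused.
#' @return A tibble with one row per replicate-parameter pair: `rep`,
#'   `converged`, `parameter`, `estimate`, `true_value`.
#' @export
tidy.tmdd_sse <- function(x, ...) {
  truth <- estimated_values(x$true_params)
  x$estimates |>
    tidyr::pivot_longer(-c("rep", "converged", "objective"),
                        names_to = "parameter", values_to = "estimate") |>
    dplyr::mutate(true_value = unname(truth[.data$parameter])) |>
    dplyr::select("rep", "converged", "parameter", "estimate", "true_value")
}

#' One-row summary of an SSE result
#'
#' @param x A `tmdd_sse` object.
#' @param ... Unused.
#' @return A tibble with the design id, replicate counts and the average
#'   empirical %RSE with non-converged replicates included and excluded.
#' @export
glance.tmdd_sse <- function(x, ...) {
  avg_all <- attr(empirical_rse(x), "average")
  avg_conv <- if (x$n_converged >= 2) {
    attr(empirical_rse(x, exclude_nonconverged = TRUE), "average")
  } else {
    NA_real_
  }
  tibble::tibble(design_id = x$design_id, n_requested = x$n_requested,
                 n_converged = x$n_converged, avg_rse_pct = avg_all,
                 avg_rse_pct_converged = avg_conv)
}

#' Tidy a Fisher information matrix
#'
#' @param x A `tmdd_fim` object.
#' @param ... Unused.
#' @return A long tibble of matrix entries (`row`, `col`, `value`).
#' @export
tidy.tmdd_fim <- function(x, ...) {
  tibble::tibble(
    row = rep(x$param_order, times = x$p),
    col = rep(x$param_order, each = x$p),
    value = c(x$fim)
  )
}

#' One-row summary of a Fisher information matrix
#'
#' @param x A `tmdd_fim` object.
#' @param ... Unused.
#' @return A tibble with `design_id`, `p` and `log_det`.
#' @export
glance.tmdd_fim <- function(x, ...) {
  tibble::tibble(design_id = x$design_id, p = x$p,
                 log_det = as.numeric(x$log_det))
}

#' Tidy a model fit
#'
#' @param x A `tmdd_fit` object.
#' @param ... Unused.
#' @return A tibble with `parameter` and `estimate` (natural scale).
#' @export
tidy.tmdd_fit <- function(x, ...) {
  tibble::tibble(parameter = x$labels, estimate = unname(x$estimate))
}

#' One-row summary of a model fit
#'
#' @param x A `tmdd_fit` object.
#' @param ... Unused.
#' @return A tibble with the convergence flag and the FO -2 log-likelihood.
#' @export
glance.tmdd_fit <- function(x, ...) {
  tibble::tibble(converged = x$converged, objective = x$objective)
}

#' Tidy a line-search optimization trace
#'
#' @param x A `tmdd_ls` object.
#' @param ... Unused.
#' @return The criterion trace tibble (`step`, `log_det`).
#' @export
tidy.tmdd_ls <- function(x, ...) x$criterion_trace

#' One-row summary of a line-search optimization
#'
#' @param x A `tmdd_ls` object.
#' @param ... Unused.
#' @return A tibble with initial/final log-determinants, accepted moves and
#'   cycle count.
#' @export
glance.tmdd_ls <- function(x, ...) {
  tr <- x$criterion_trace$log_det
  tibble::tibble(design_id = x$initial_design$id,
                 log_det_initial = tr[1], log_det_final = tr[length(tr)],
                 n_moves = length(tr) - 1, n_cycles = x$n_cycles)
}

#' Tidy a decision-metric result
#'
#' @param x A `tmdd_decision` object.
#' @param ... Unused.
#' @return The per-dose error-probability tibble (`dose_mg`, `p_incorrect`).
#' @export
tidy.tmdd_decision <- function(x, ...) x$per_dose

#' One-row summary of a decision-metric result
#'
#' @param x A `tmdd_decision` object.
#' @param ... Unused.
#' @return A tibble with `true_dose`, `threshold`, `n_vectors` and the
#'   overall `p_incorrect`.
#' @export
glance.tmdd_decision <- function(x, ...) {
  tibble::tibble(true_dose = x$true_dose, threshold = x$threshold,
                 n_vectors = nrow(x$incorrect), p_incorrect = x$p_incorrect)
}
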