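## Approximate maximum-likelihood estimation of the population model by the
## first-order (FO) method: the marginal distribution of a subject's
## observation vector is approximated as Gaussian with mean the typical
## prediction and covariance J_eta Omega J_eta' + diag(sigma2 f^2), the same
## linearization used for the FIM. All positive parameters are estimated on
## the log scale (box constraints via the transform).

## step for the central eta finite differences inside the objective
ETA_FD_STEP <- 1e-2

## order observations within a subject: analyte within time
arrange_dataset <- function(data) {
  data[order(data$id, data$time, match(data$analyte, tmdd_analytes())), ]
}

## deterministic structural zeros (pre-dose total drug): no information
## under proportional error, excluded from likelihood and FIM alike
is_structural_zero <- function(time, analyte) time == 0 & analyte == "OMA_TOT"

prepare_fit_data <- function(data) {
  data <- arrange_dataset(data)
  ids <- unique(data$id)
  first <- data[data$id == ids[1], ]
  n_obs <- nrow(first)
  if (nrow(data) != n_obs * length(ids)) {
    stop("all subjects must share the design's sampling schedule")
  }
  analytes <- intersect(tmdd_analytes(), unique(data$analyte))
  keep <- !is_structural_zero(first$time, first$analyte)
  y <- matrix(data$dv, nrow = n_obs)[keep, , drop = FALSE]
  dose <- data$dose_mg[match(ids, data$id)]
  list(times = first$time[keep], analytes_row = first$analyte[keep],
       analytes = analytes, y = y, dose = dose,
       doses = sort(unique(dose)))
}

## objective: -2 log marginal likelihood under the FO approximation
fo_objective <- function(x, prep, template, labels, rtol, atol) {
  ## reject absurd iterates before they reach the integrator
  if (any(!is.finite(x)) || any(abs(x) > 30)) return(1e10)
  params <- tryCatch(vec_to_params(exp(x), labels, template),
                     error = function(e) NULL)
  if (is.null(params)) return(1e10)
  eta_names <- names(params$omega2)
  utimes <- sort(unique(prep$times))

  ## stacked solve: per dose, base + central eta perturbations
  blocks <- list()
  for (d in prep$doses) {
    blocks <- c(blocks, list(list(theta = params$theta, dose_mg = d)))
    for (k in eta_names) {
      up <- stats::setNames(ETA_FD_STEP, k)
      blocks <- c(blocks,
                  list(list(theta = apply_eta(params, up), dose_mg = d)),
                  list(list(theta = apply_eta(params, -up), dose_mg = d)))
    }
  }
  pr <- tryCatch(
    suppressWarnings(predict_blocks(params, blocks, utimes, rtol, atol)),
    error = function(e) NULL)
  if (is.null(pr) || anyNA(pr)) return(1e10)

  row_t <- match(prep$times, utimes)
  row_a <- match(prep$analytes_row, tmdd_analytes())
  sel <- cbind(row_t, row_a)
  per_dose <- 1 + 2 * length(eta_names)
  total <- 0
  for (di in seq_along(prep$doses)) {
    b0 <- (di - 1) * per_dose + 1
    f <- pr[, b0, ][sel]
    je <- vapply(seq_along(eta_names), function(k) {
      (pr[, b0 + 2 * k - 1, ][sel] - pr[, b0 + 2 * k, ][sel]) / (2 * ETA_FD_STEP)
    }, numeric(length(f)))
    var_res <- params$sigma2[prep$analytes_row] * f^2
    if (any(var_res <= 0) || any(!is.finite(var_res))) return(1e10)
    v <- je %*% (params$omega2[eta_names] * t(je)) +
      diag(var_res, nrow = length(f))
    ch <- tryCatch(chol(v), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    log_det <- 2 * sum(log(diag(ch)))
    cols <- which(prep$dose == prep$doses[di])
    r <- prep$y[, cols, drop = FALSE] - f
    z <- backsolve(ch, r, transpose = TRUE)
    total <- total + length(cols) * (log_det + length(f) * log(2 * pi)) +
      sum(z^2)
  }
  if (!is.finite(total)) return(1e10)
  total
}

## map an estimation vector (natural scale) + labels back onto a tmdd_params
vec_to_params <- function(v, labels, template) {
  th <- template$theta
  om <- template$omega2
  sg <- template$sigma2
  for (i in seq_along(labels)) {
    lb <- labels[i]
    if (startsWith(lb, "omega2_")) {
      om[sub("omega2_", "", lb)] <- v[i]
    } else if (startsWith(lb, "sigma2_")) {
      sg[sub("sigma2_", "", lb)] <- v[i]
    } else {
      th[lb] <- v[i]
    }
  }
  tmdd_params(th, om, sg, fixed = template$fixed, mw = template$mw)
}

#' Fit the population model to a dataset (FO approximate ML)
#'
#' Maximizes the FO-approximated marginal likelihood over the estimated
#' fixed effects and the variance parameters (all log-transformed). The
#' residual variance of an analyte absent from the data is not estimated.
#' Optimizer failures are reported through the `converged` flag, never as
#' errors, so that simulation-estimation loops keep running.
#'
#' @param data A `tmdd_dataset` tibble (see [simulate_dataset()]).
#' @param init A [tmdd_params] object providing starting values and the
#'   estimation structure (which effects are fixed, which carry IIV).
#' @param rtol,atol Integrator tolerances used inside the objective (looser
#'   than the prediction defaults: estimation is FD-gradient driven).
#' @param maxit Iteration cap for [stats::optim()] (BFGS).
#' @return An object of class `tmdd_fit`: list with `estimate` (named
#'   vector on the natural scale), `converged`, `objective` (-2 log
#'   likelihood, FO) and `labels`.
#' @export
fit_dataset <- function(data, init, rtol = 1e-6, atol = 1e-8, maxit = 300) {
  stopifnot(inherits(init, "tmdd_params"))
  prep <- prepare_fit_data(data)
  labels <- estimated_labels(init, prep$analytes)
  x0 <- log(estimated_values(init, prep$analytes)[labels])
  res <- tryCatch(
    stats::optim(x0, fo_objective, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-10),
                 prep = prep, template = init, labels = labels,
                 rtol = rtol, atol = atol),
    error = function(e) NULL
  )
  if (is.null(res)) {
    est <- exp(x0)
    structure(list(estimate = stats::setNames(est, labels), converged = FALSE,
                   objective = NA_real_, labels = labels),
              class = "tmdd_fit")
  } else {
    structure(list(estimate = stats::setNames(exp(res$par), labels),
                   converged = res$convergence == 0,
                   objective = res$value, labels = labels),
              class = "tmdd_fit")
  }
}

#' Stochastic simulation and estimation (SSE)
#'
#' Repeats `n_reps` independent simulate-then-refit cycles under a design:
#' each replicate simulates a dataset from the true parameters with
#' [simulate_dataset()] and re-estimates the model with [fit_dataset()]
#' (initial values at the truth, standard SSE practice). The replicate
#' estimate vectors are the raw material for empirical precision
#' ([empirical_rse()]), population prediction areas
#' ([population_prediction_area()]) and the dose-selection decision metric
#' ([decision_probability()]).
#'
#' @param params True [tmdd_params].
#' @param design A [tmdd_design].
#' @param n_reps Number of replicates (>= 2).
#' @param seed Integer; replicate seeds are derived from it deterministically.
#' @param verbose Print one line per replicate.
#' @inheritParams fit_dataset
#' @return An object of class `tmdd_sse`: list with `design_id`,
#'   `estimates` (tibble: `rep`, `converged`, `objective`, one column per
#'   estimated parameter), `true_params`, `n_requested`, `n_converged`,
#'   `seeds`.
#' @export
run_sse <- function(params, design, n_reps = 100, seed = 1, verbose = FALSE,
                    rtol = 1e-6, atol = 1e-8, maxit = 300) {
  stopifnot(n_reps >= 2)
  seeds <- vapply(seq_len(n_reps),
                  function(r) as.integer((abs(seed) + 7717 * r) %% 2147483647L),
                  integer(1))
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    data <- simulate_dataset(params, design, seeds[r])
    fit <- fit_dataset(data, init = params, rtol = rtol, atol = atol,
                       maxit = maxit)
    rows[[r]] <- dplyr::bind_cols(
      tibble::tibble(rep = r, converged = fit$converged,
                     objective = fit$objective),
      tibble::as_tibble(as.list(fit$estimate))
    )
    if (verbose) {
      message(sprintf("replicate %d/%d: converged = %s", r, n_reps,
                      fit$converged))
    }
  }
  est <- dplyr::bind_rows(rows)
  structure(
    list(design_id = design$id, estimates = est, true_params = params,
         n_requested = n_reps, n_converged = sum(est$converged),
         seeds = seeds),
    class = "tmdd_sse"
  )
}

#' Empirical relative standard errors from an SSE run
#'
#' `%RSE_j = 100 sd(estimates_j) / |true_j|`: the replicate-to-replicate
#' spread of each parameter relative to the simulation truth. The overall
#' precision (attribute `average`) is the arithmetic mean over all estimated
#' fixed- and random-effect parameters. Non-converged replicates are
#' included by default (set `exclude_nonconverged` to drop them; both
#' variants are worth reporting since optimizer failures concentrate in
#' poorly informative designs).
#'
#' @param sse A `tmdd_sse` object.
#' @param exclude_nonconverged Drop replicates whose fit did not converge.
#' @return A tibble with `parameter`, `true_value`, `rse_pct`; attributes
#'   `average` and `n_used`.
#' @export
empirical_rse <- function(sse, exclude_nonconverged = FALSE) {
  stopifnot(inherits(sse, "tmdd_sse"))
  est <- sse$estimates
  if (exclude_nonconverged) est <- est[est$converged, ]
  if (nrow(est) < 2) stop("need at least 2 usable replicates")
  labels <- setdiff(names(est), c("rep", "converged", "objective"))
  truth <- estimated_values(sse$true_params)[labels]
  rse <- vapply(labels, function(l) 100 * stats::sd(est[[l]]) / abs(truth[[l]]),
                numeric(1))
  out <- tibble::tibble(parameter = labels, true_value = unname(truth),
                        rse_pct = unname(rse))
  attr(out, "average") <- mean(out$rse_pct)
  attr(out, "n_used") <- nrow(est)
  out
}

#' @export
print.tmdd_fit <- function(x, ...) {
  cat("<tmdd_fit> converged:", x$converged,
      "| -2LL (FO):", format(x$objective, digits = 8), "\n")
  print(x$estimate)
  invisible(x)
}

#' @export
print.tmdd_sse <- function(x, ...) {
  cat("<tmdd_sse> design", x$design_id, "|", x$n_requested, "replicates,",
      x$n_converged, "converged\n")
  invisible(x)
}

## full fixed-effect vectors (theta) for each SSE replicate, with
## non-estimated effects held at the truth
sse_theta_sets <- function(sse) {
  est <- sse$estimates
  template <- sse$true_params
  th_lab <- intersect(names(est), names(template$theta))
  lapply(seq_len(nrow(est)), function(r) {
    th <- template$theta
    th[th_lab] <- unlist(est[r, th_lab])
    th
  })
}
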