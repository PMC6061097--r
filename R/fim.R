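## Population Fisher information under the first-order (FO) approximation.
##
## For one subject of a group the observation vector (analyte within time)
## is modelled as y ~ N(f(theta), V) with f the typical prediction and
## V = (df/deta) Omega (df/deta)' + diag(sigma2_a f^2)   (proportional error),
## derivatives taken at eta = 0. The *reduced* FIM is block-diagonal across
## {fixed effects} and {omega2, sigma2}: the fixed block is J' V^-1 J and
## the variance block is 1/2 tr(V^-1 dV/dl_i V^-1 dV/dl_j).

## relative step for central finite differences on fixed effects
FD_REL_STEP <- 1e-4

## Sensitivities of the three analytes for one dose group at `times`:
## f [time, analyte], Jtheta [time, analyte, p_theta], Jeta [time, analyte, n_eta].
## Random effects are log-normal, so df/deta_k = theta_k * df/dtheta_k at eta=0.
model_sensitivities <- function(params, dose_mg, times, rel_step = FD_REL_STEP,
                                rtol = 1e-8, atol = 1e-10) {
  th_est <- estimated_theta(params)
  if (!all(names(params$omega2) %in% th_est)) {
    stop("parameters carrying IIV must be estimated fixed effects")
  }
  base <- params$theta
  blocks <- vector("list", 1 + 2 * length(th_est))
  blocks[[1]] <- list(theta = base, dose_mg = dose_mg)
  h <- rel_step * abs(base[th_est])
  for (i in seq_along(th_est)) {
    up <- base; up[th_est[i]] <- up[th_est[i]] + h[i]
    dn <- base; dn[th_est[i]] <- dn[th_est[i]] - h[i]
    blocks[[2 * i]] <- list(theta = up, dose_mg = dose_mg)
    blocks[[2 * i + 1]] <- list(theta = dn, dose_mg = dose_mg)
  }
  pr <- predict_blocks(params, blocks, times, rtol, atol)
  f <- pr[, 1, , drop = TRUE]
  f <- matrix(f, length(times), 3, dimnames = list(NULL, tmdd_analytes()))
  jt <- array(NA_real_, c(length(times), 3, length(th_est)),
              dimnames = list(NULL, tmdd_analytes(), th_est))
  for (i in seq_along(th_est)) {
    jt[, , i] <- (pr[, 2 * i, ] - pr[, 2 * i + 1, ]) / (2 * h[i])
  }
  eta_names <- names(params$omega2)
  je <- array(NA_real_, c(length(times), 3, length(eta_names)),
              dimnames = list(NULL, tmdd_analytes(), eta_names))
  for (k in seq_along(eta_names)) {
    je[, , k] <- base[eta_names[k]] * jt[, , eta_names[k]]
  }
  list(times = times, f = f, jtheta = jt, jeta = je)
}

## FIM contribution of `n_subjects` subjects of one group, for observations
## at times[time_idx] (duplicates allowed) of `analytes`. `sens` must have
## been computed at sens$times; time_idx indexes into it.
assemble_group_fim <- function(sens, time_idx, analytes, params, n_subjects) {
  th_est <- estimated_theta(params)
  eta_names <- names(params$omega2)
  sig_names <- intersect(names(params$sigma2), analytes)
  a_idx <- match(analytes, tmdd_analytes())

  ## stack analyte-within-time
  rows_t <- rep(time_idx, each = length(analytes))
  rows_a <- rep(a_idx, times = length(time_idx))
  f <- sens$f[cbind(rows_t, rows_a)]
  jt <- matrix(sens$jtheta[cbind(rep(rows_t, length(th_est)),
                                 rep(rows_a, length(th_est)),
                                 rep(seq_along(th_est), each = length(f)))],
               ncol = length(th_est), dimnames = list(NULL, th_est))
  je <- matrix(sens$jeta[cbind(rep(rows_t, length(eta_names)),
                               rep(rows_a, length(eta_names)),
                               rep(seq_along(eta_names), each = length(f)))],
               ncol = length(eta_names), dimnames = list(NULL, eta_names))
  sig_row <- params$sigma2[tmdd_analytes()[rows_a]]
  var_res <- sig_row * f^2

  ## structural zeros (pre-dose drug) carry no information under
  ## proportional error: drop them rather than regularize
  keep <- var_res > 0
  if (!any(keep)) stop("design has no informative observations")
  f <- f[keep]; jt <- jt[keep, , drop = FALSE]; je <- je[keep, , drop = FALSE]
  var_res <- var_res[keep]; rows_a <- rows_a[keep]

  v <- je %*% (params$omega2[eta_names] * t(je)) + diag(var_res, nrow = length(f))
  ch <- tryCatch(chol(v), error = function(e) {
    stop("singular FO variance matrix for this design (", conditionMessage(e), ")")
  })
  vinv <- chol2inv(ch)

  labels <- c(th_est, paste0("omega2_", eta_names), paste0("sigma2_", sig_names))
  p <- length(labels)
  fim <- matrix(0, p, p, dimnames = list(labels, labels))

  ## fixed-effect block
  fim[th_est, th_est] <- n_subjects * crossprod(jt, vinv %*% jt)

  ## variance block: dV/domega2_k = u_k u_k', dV/dsigma2_a = diag(f^2 1_a)
  w <- vinv %*% je                                      # columns w_k = V^-1 u_k
  utvu <- crossprod(je, w)                              # u_k' V^-1 u_l
  om_lab <- paste0("omega2_", eta_names)
  fim[om_lab, om_lab] <- n_subjects / 2 * utvu^2
  d_list <- lapply(sig_names, function(a) f^2 * (rows_a == match(a, tmdd_analytes())))
  sg_lab <- paste0("sigma2_", sig_names)
  for (i in seq_along(sig_names)) {
    di <- d_list[[i]]
    ## omega2 x sigma2: w_k' D_a w_k
    fim[om_lab, sg_lab[i]] <- n_subjects / 2 * colSums(w^2 * di)
    fim[sg_lab[i], om_lab] <- fim[om_lab, sg_lab[i]]
    for (j in seq_len(i)) {
      val <- n_subjects / 2 * sum(vinv^2 * outer(d_list[[j]], di))
      fim[sg_lab[i], sg_lab[j]] <- val
      fim[sg_lab[j], sg_lab[i]] <- val
    }
  }
  fim
}

#' Individual Fisher information for one dose group
#'
#' FO-approximated information contributed by a single subject of a dose
#' group observed at `times` for `analytes`. The reduced parameterization is
#' used: the fixed-effect and variance-parameter blocks are computed and the
#' cross-block is identically zero.
#'
#' @param params A [tmdd_params] object.
#' @param dose_mg Dose of the group (mg).
#' @param times Sampling days (duplicates allowed).
#' @param analytes Measured analytes.
#' @return A symmetric p x p matrix with parameter labels (fixed effects,
#'   then `omega2_*`, then `sigma2_*` for the measured analytes).
#' @export
individual_fim <- function(params, dose_mg, times, analytes = tmdd_analytes()) {
  times <- sort(times)
  ut <- sort(unique(times))
  sens <- model_sensitivities(params, dose_mg, ut)
  assemble_group_fim(sens, match(times, ut), analytes, params, n_subjects = 1)
}

#' Population Fisher information of a design
#'
#' Sums the per-group individual FIMs weighted by group sizes. Residual
#' variances of analytes the design does not measure are not estimable and
#' are excluded from the parameter set; everything else (8 estimated fixed
#' effects, 3 IIV variances, one proportional residual variance per measured
#' analyte for the packaged model) is included. The parameter count `p` is
#' taken from the parameter file contents, never hard-coded.
#'
#' @param params A [tmdd_params] object.
#' @param design A [tmdd_design] object.
#' @param rtol,atol Integrator tolerances.
#' @return An object of class `tmdd_fim`: list with elements `fim`
#'   (labelled symmetric matrix), `p`, `log_det`, `param_order` and
#'   `design_id`.
#' @examples
#' \donttest{
#' p <- omalizumab_params()
#' f1 <- population_fim(p, design_catalogue("1"))
#' f1$p
#' }
#' @export
population_fim <- function(params, design, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "tmdd_params"), inherits(design, "tmdd_design"))
  times <- design$sample_times
  ut <- sort(unique(times))
  fim <- NULL
  for (g in seq_len(nrow(design$groups))) {
    sens <- model_sensitivities(params, design$groups$dose_mg[g], ut,
                                rtol = rtol, atol = atol)
    contrib <- assemble_group_fim(sens, match(times, ut), design$analytes,
                                  params, design$groups$n_subjects[g])
    fim <- if (is.null(fim)) contrib else fim + contrib
  }
  new_tmdd_fim(fim, design$id)
}

new_tmdd_fim <- function(fim, design_id = NA_character_) {
  structure(
    list(fim = fim, p = nrow(fim), log_det = d_criterion(fim),
         param_order = rownames(fim), design_id = design_id),
    class = "tmdd_fim"
  )
}

#' D-criterion (log-determinant) of a Fisher information matrix
#'
#' Returns the log-determinant of the FIM, the quantity maximized by
#' D-optimal design. The log scale avoids overflow for the 10--15 parameter
#' models handled here; a singular (or non-positive-definite) FIM yields
#' `-Inf` with attribute `singular = TRUE` rather than an error.
#'
#' @param fim A `tmdd_fim` object or a symmetric matrix.
#' @return Log-determinant (scalar).
#' @export
d_criterion <- function(fim) {
  m <- if (inherits(fim, "tmdd_fim")) fim$fim else fim
  dt <- determinant(m, logarithm = TRUE)
  if (dt$sign <= 0 || !is.finite(dt$modulus)) {
    out <- -Inf
    attr(out, "singular") <- TRUE
    return(out)
  }
  as.numeric(dt$modulus)
}

#' D-efficiency of a design relative to a reference design
#'
#' \deqn{\mathrm{eff} = (|FIM| / |FIM^*|)^{1/p}} with `*` the reference.
#' An efficiency of 0.5 means the candidate design would need twice the
#' subjects to match the reference's expected parameter precision. When the
#' two FIMs estimate different parameter sets (a design omitting an analyte
#' cannot estimate that analyte's residual variance), the comparison is made
#' on the common estimable subset and `p` is its size.
#'
#' @param fim,fim_ref `tmdd_fim` objects (candidate and reference).
#' @return Efficiency as a fraction, with attribute `p` used.
#' @export
efficiency <- function(fim, fim_ref) {
  stopifnot(inherits(fim, "tmdd_fim"), inherits(fim_ref, "tmdd_fim"))
  common <- intersect(fim$param_order, fim_ref$param_order)
  if (length(common) == 0) stop("designs share no estimable parameters")
  ld <- d_criterion(fim$fim[common, common, drop = FALSE])
  ld_ref <- d_criterion(fim_ref$fim[common, common, drop = FALSE])
  out <- exp((ld - ld_ref) / length(common))
  attr(out, "p") <- length(common)
  out
}

#' FIM-predicted relative standard errors
#'
#' Cramer-Rao lower-bound prediction of per-parameter precision:
#' `%RSE_j = 100 sqrt([FIM^-1]_jj) / |value_j|`, with variance parameters on
#' the variance scale. The average over all estimated parameters is attached
#' as attribute `average` (this is the fast asymptotic counterpart of the
#' empirical SSE-based [empirical_rse()]).
#'
#' @param fim A `tmdd_fim` object.
#' @param params The [tmdd_params] the FIM was evaluated at.
#' @return A tibble with `parameter`, `true_value`, `rse_pct`, plus
#'   attribute `average`.
#' @export
predicted_rse <- function(fim, params) {
  stopifnot(inherits(fim, "tmdd_fim"))
  vals <- estimated_values(params)[fim$param_order]
  inv <- tryCatch(chol2inv(chol(fim$fim)), error = function(e) NULL)
  if (is.null(inv)) {
    rse <- rep(Inf, fim$p)
  } else {
    rse <- 100 * sqrt(pmax(diag(inv), 0)) / abs(vals)
  }
  out <- tibble::tibble(parameter = fim$param_order,
                        true_value = unname(vals), rse_pct = unname(rse))
  attr(out, "average") <- mean(out$rse_pct)
  out
}

#' @export
print.tmdd_fim <- function(x, ...) {
  cat("<tmdd_fim> design", x$design_id, "| p =", x$p,
      "| log det =", format(x$log_det, digits = 8), "\n")
  invisible(x)
}
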