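#' Free concentrations under the quasi-equilibrium binding assumption
#'
#' Given total drug and total target concentrations, partitions them into
#' free drug, free target and complex assuming 1:1 binding at instantaneous
#' equilibrium with dissociation constant `kd`. All three inputs must share
#' one (molar-equivalent) concentration unit. The free drug is the positive
#' root of the equilibrium quadratic,
#' \deqn{D_f = \tfrac12\big[(D_t - R_t - K_D) +
#'   \sqrt{(D_t - R_t - K_D)^2 + 4 K_D D_t}\big],}
#' evaluated on its numerically stable branch.
#'
#' @param d_tot,r_tot Total drug / total target concentrations (vectors are
#'   recycled to a common length).
#' @param kd Equilibrium dissociation constant, same unit, `> 0`.
#' @return A tibble with columns `drug_free`, `target_free` and `complex`.
#' @examples
#' qe_free_concentrations(10, 2.2, 1.6)
#' @export
qe_free_concentrations <- function(d_tot, r_tot, kd) {
  n <- max(length(d_tot), length(r_tot), length(kd))
  d_tot <- rep_len(d_tot, n); r_tot <- rep_len(r_tot, n); kd <- rep_len(kd, n)
  if (any(d_tot < 0) || any(r_tot < 0)) stop("d_tot and r_tot must be non-negative")
  if (any(kd <= 0)) stop("kd must be strictly positive")
  drug_free <- qe_free_drug(d_tot, r_tot, kd)
  cmplx <- pmax(d_tot - drug_free, 0)
  target_free <- pmax(r_tot - cmplx, 0)
  tibble::tibble(drug_free = drug_free, target_free = target_free, complex = cmplx)
}

## stable positive root of the QE quadratic (vectorized)
qe_free_drug <- function(d_tot, r_tot, kd) {
  b <- d_tot - r_tot - kd
  disc <- sqrt(b * b + 4 * kd * d_tot)
  out <- ifelse(b <= 0,
                ifelse(disc - b > 0, 2 * kd * d_tot / (disc - b), 0),
                0.5 * (b + disc))
  pmax(out, 0)
}

#' Time derivative of the QE TMDD state
#'
#' The reference R implementation of the model right-hand side, used for
#' cross-checking the compiled integrator. States: `A_depot` (amount at the
#' subcutaneous site, nmol), `D_tot` (total drug, nM), `R_tot` (total
#' target, nM). Drug is absorbed first order from the depot; free drug is
#' cleared with `CL_OMA`, complex with `CL_COMP`; target turnover has a
#' zero-order synthesis fixing `R_tot = R0` at the drug-free steady state
#' and elimination `(CL_IGE/V) R0 (R_free/R0)^alpha` plus complex clearance.
#'
#' @param state Numeric vector `c(A_depot, D_tot, R_tot)`; non-negative.
#' @param params A [tmdd_params] object.
#' @param eta Optional named random effects (log scale) on parameters with
#'   IIV.
#' @return Numeric vector of derivatives (per day).
#' @export
tmdd_rhs <- function(state, params, eta = NULL) {
  stopifnot(inherits(params, "tmdd_params"), length(state) == 3)
  if (any(!is.finite(state))) stop("non-finite state passed to tmdd_rhs")
  th <- apply_eta(params, eta)
  A <- state[1]; d_tot <- max(state[2], 0); r_tot <- max(state[3], 0)
  r0 <- r0_nm(params)
  d_free <- qe_free_drug(d_tot, r_tot, th[["KD"]])
  cmplx <- d_tot - d_free
  r_free <- max(r_tot - cmplx, 0)
  ke_o <- th[["CL_OMA"]] / th[["V"]]
  ke_i <- th[["CL_IGE"]] / th[["V"]]
  ke_c <- th[["CL_COMP"]] / th[["V"]]
  loss <- if (r_free > 0) ke_i * r0 * (r_free / r0)^th[["alpha"]] else 0
  c(A_depot = -th[["ka"]] * A,
    D_tot = th[["ka"]] * A / th[["V"]] - ke_o * d_free - ke_c * cmplx,
    R_tot = ke_i * r0 - loss - ke_c * cmplx)
}

## individual fixed effects: typical * exp(eta) on IIV-carrying parameters
apply_eta <- function(params, eta) {
  th <- params$theta
  if (is.null(eta) || length(eta) == 0) return(th)
  if (is.null(names(eta)) || !all(names(eta) %in% names(params$omega2))) {
    stop("eta must be named and restricted to parameters with IIV: ",
         paste(names(params$omega2), collapse = ", "))
  }
  th[names(eta)] <- th[names(eta)] * exp(unlist(eta))
  th
}

## ---- batched compiled integrator -------------------------------------------

## maximum number of model instances per compiled call (see src/tmdd_ode.c)
TMDD_MAXBLK <- 128L

## Integrate a list of blocks, each list(theta = full named fixed effects,
## dose_mg = scalar). Returns array [time, block, state(A, D, R)].
## `mw` conversions are taken from `params`; per-block theta may differ
## (eta-perturbed or estimation iterates).
solve_blocks <- function(params, blocks, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(length(blocks) >= 1)
  tt <- sort(unique(c(0, times)))
  if (length(tt) == 1) tt <- c(tt, tt + 1)  # lsoda needs at least two times
  nblk_total <- length(blocks)
  out <- array(NA_real_, c(length(tt), nblk_total, 3))
  for (start in seq(1, nblk_total, by = TMDD_MAXBLK)) {
    idx <- start:min(start + TMDD_MAXBLK - 1L, nblk_total)
    chunk <- blocks[idx]
    nblk <- length(chunk)
    parms <- numeric(1 + 8 * TMDD_MAXBLK)
    parms[1] <- nblk
    y0 <- numeric(3 * nblk)
    for (b in seq_len(nblk)) {
      th <- chunk[[b]]$theta
      r0 <- th[["R0"]] * 1000 / params$mw[["ige"]]
      parms[1 + 8 * (b - 1) + 1:8] <- c(
        th[["ka"]], th[["V"]],
        th[["CL_OMA"]] / th[["V"]], th[["CL_IGE"]] / th[["V"]],
        th[["CL_COMP"]] / th[["V"]], th[["KD"]], r0, th[["alpha"]])
      y0[3 * (b - 1) + 1:3] <- c(
        th[["F"]] * chunk[[b]]$dose_mg * 1e6 / params$mw[["oma"]], 0, r0)
    }
    ## blocks are independent, so the stacked Jacobian is block-diagonal
    ## with 3x3 blocks: banded (bandwidth 2) keeps lsoda's implicit steps cheap
    sol <- deSolve::ode(y = y0, times = tt, func = "tmdd_derivs",
                        parms = parms, dllname = "tmddesign",
                        initfunc = "tmdd_init", method = "lsoda",
                        jactype = "bandint", bandup = 2, banddown = 2,
                        rtol = rtol, atol = atol, maxsteps = 50000)
    if (nrow(sol) < length(tt) || anyNA(sol)) {
      stop("ODE integration failed (lsoda did not reach all requested times)")
    }
    ## deSolve columns are y1..y(3*nblk): state varies fastest within a block
    out[, idx, ] <- aperm(array(sol[, -1], c(length(tt), 3, nblk)), c(1, 3, 2))
  }
  ## map back to requested (possibly duplicated, unsorted) times
  out[match(times, tt), , , drop = FALSE]
}

## predictions for many blocks at shared times:
## returns array [time, block, analyte]
predict_blocks <- function(params, blocks, times, rtol = 1e-8, atol = 1e-10) {
  st <- solve_blocks(params, blocks, times, rtol, atol)
  nt <- length(times); nb <- length(blocks)
  kd <- rep(vapply(blocks, function(b) b$theta[["KD"]], numeric(1)), each = nt)
  d_tot <- pmax(matrix(st[, , 2], nt, nb), 0)
  r_tot <- pmax(matrix(st[, , 3], nt, nb), 0)
  d_free <- qe_free_drug(d_tot, r_tot, kd)
  cmplx <- pmax(d_tot - d_free, 0)
  r_free <- pmax(r_tot - cmplx, 0)
  sc <- analyte_scale(params)
  array(c(d_tot * sc[["OMA_TOT"]], r_free * sc[["IGE_FREE"]],
          r_tot * sc[["IGE_TOT"]]),
        c(nt, nb, 3), dimnames = list(NULL, NULL, tmdd_analytes()))
}

## ---- user-facing predictions ------------------------------------------------

#' Typical-subject analyte predictions
#'
#' Solves the QE TMDD model for a typical subject (all random effects zero)
#' after a single subcutaneous dose and returns the three analytes --- total
#' drug, free target and total target --- in ng/mL at the requested times.
#' The day-0 sample is pre-dose: at `t = 0` total drug is 0 and both IgE
#' analytes equal the baseline `R0`.
#'
#' @param params A [tmdd_params] object.
#' @param dose_mg Subcutaneous dose in mg (`>= 0`).
#' @param times Sampling times in days, non-negative.
#' @param rtol,atol Integrator tolerances (lsoda).
#' @return A tibble of class `tmdd_trajectory` with columns `time`,
#'   `analyte`, `value` (ng/mL) and a `dose_mg` attribute.
#' @examples
#' p <- omalizumab_params()
#' typical_prediction(p, dose_mg = 150, times = c(0, 14, 84))
#' @export
typical_prediction <- function(params, dose_mg, times, rtol = 1e-8, atol = 1e-10) {
  individual_prediction(params, eta = NULL, dose_mg = dose_mg, times = times,
                        rtol = rtol, atol = atol)
}

#' Individual analyte predictions
#'
#' As [typical_prediction()], but for a subject with log-normal random
#' effects `eta`: the individual value of each IIV-carrying parameter is
#' `typical * exp(eta)`. `eta = NULL` (or all zero) reproduces the typical
#' prediction exactly.
#'
#' @inheritParams typical_prediction
#' @param eta Named numeric vector of random effects; names must be among
#'   the parameters carrying IIV (`names(params$omega2)`).
#' @return A tibble of class `tmdd_trajectory`.
#' @export
individual_prediction <- function(params, eta, dose_mg, times,
                                  rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "tmdd_params"))
  if (dose_mg < 0) stop("dose_mg must be non-negative")
  if (any(times < 0)) stop("times must be non-negative")
  th <- apply_eta(params, eta)
  pr <- predict_blocks(params, list(list(theta = th, dose_mg = dose_mg)),
                       times, rtol, atol)[, 1, , drop = TRUE]
  pr <- matrix(pr, nrow = length(times), ncol = 3,
               dimnames = list(NULL, tmdd_analytes()))
  out <- tibble::tibble(
    time = rep(times, times = 3L),
    analyte = rep(tmdd_analytes(), each = length(times)),
    value = c(pr)
  )
  attr(out, "dose_mg") <- dose_mg
  class(out) <- c("tmdd_trajectory", class(out))
  out
}

#' Terminal half-life of total drug
#'
#' Simulates a long single-dose typical profile and estimates the terminal
#' log-linear half-life of total drug by ordinary regression of
#' `log(OMA_TOT)` on time over the tail of the curve.
#'
#' @inheritParams typical_prediction
#' @param dose_mg Reference dose (default 150 mg; the terminal slope is
#'   dose-independent once binding is in its linear regime).
#' @param horizon Simulation length in days.
#' @param tail_frac Fraction of the horizon (from the end) used for the
#'   regression.
#' @return Half-life in days, with attribute `r.squared` of the tail
#'   regression. A warning is raised if the tail is not log-linear
#'   (R squared below 0.995).
#' @examples
#' terminal_half_life(omalizumab_params())
#' @export
terminal_half_life <- function(params, dose_mg = 150, horizon = 300,
                               tail_frac = 0.3) {
  times <- seq(0, horizon, by = 1)
  tr <- typical_prediction(params, dose_mg, times)
  oma <- tr$value[tr$analyte == "OMA_TOT"]
  keep <- times >= (1 - tail_frac) * horizon & oma > 0
  fit <- stats::lm(log(oma[keep]) ~ times[keep])
  r2 <- summary(fit)$r.squared
  if (r2 < 0.995) {
    warning("terminal phase not log-linear (R^2 = ", signif(r2, 4), ")")
  }
  out <- unname(log(2) / -stats::coef(fit)[2])
  attr(out, "r.squared") <- r2
  out
}

#' @export
print.tmdd_trajectory <- function(x, ...) {
  cat("<tmdd_trajectory> dose", attr(x, "dose_mg"), "mg\n")
  NextMethod()
}
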