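#' Simulate a trial dataset under a design
#'
#' The synthetic-data generator: draws per-subject log-normal random effects
#' `eta ~ N(0, diag(omega2))` (no correlation between parameters), computes
#' each subject's individual analyte predictions at the design's sampling
#' times, and applies the proportional residual-error model
#' `y = f (1 + eps)`, `eps ~ N(0, sigma2_analyte)`, independently per
#' observation. Pre-dose total-drug observations are structural zeros and
#' are simulated as exactly 0. Simulated values are kept as drawn (no
#' truncation or censoring), so downstream estimation must tolerate them.
#'
#' Randomness is split per subject by counter: subject `i` uses a seed
#' derived deterministically from `seed` and `i`, so the same seed gives a
#' bit-identical dataset and per-subject reproducibility holds even if
#' subjects are simulated in parallel.
#'
#' @param params A [tmdd_params] object (the "true" model).
#' @param design A [tmdd_design] object.
#' @param seed Integer seed recorded in the result.
#' @return A tibble of class `tmdd_dataset` in long format: `id`,
#'   `dose_mg`, `time`, `analyte`, `dv` (ng/mL), `pre_dose`; attributes
#'   `seed` and `design_id`. Record count equals the design's
#'   `total_samples`.
#' @examples
#' \donttest{
#' d <- simulate_dataset(omalizumab_params(), design_catalogue("12"), seed = 1)
#' nrow(d) # 480
#' }
#' @export
simulate_dataset <- function(params, design, seed) {
  stopifnot(inherits(params, "tmdd_params"), inherits(design, "tmdd_design"))
  seed <- as.integer(seed)
  times <- design$sample_times
  analytes <- design$analytes
  eta_names <- names(params$omega2)
  subjects <- tibble::tibble(
    id = seq_len(sum(design$groups$n_subjects)),
    dose_mg = rep(design$groups$dose_mg, design$groups$n_subjects)
  )

  ## per-subject substreams: deterministic counter-based seeds
  sub_seed <- function(i) as.integer((abs(seed) + 104729 * i) %% 2147483647L)
  n_obs <- length(times) * length(analytes)
  etas <- matrix(0, nrow(subjects), length(eta_names),
                 dimnames = list(NULL, eta_names))
  eps <- matrix(0, nrow(subjects), n_obs)
  for (i in seq_len(nrow(subjects))) {
    set.seed(sub_seed(i))
    etas[i, ] <- stats::rnorm(length(eta_names), 0, sqrt(params$omega2[eta_names]))
    eps[i, ] <- stats::rnorm(n_obs)
  }

  blocks <- lapply(seq_len(nrow(subjects)), function(i) {
    list(theta = apply_eta(params, etas[i, ]), dose_mg = subjects$dose_mg[i])
  })
  pr <- predict_blocks(params, blocks, times)   # [time, subject, analyte]

  out <- tidyr::expand_grid(subjects,
                            time = times,
                            analyte = analytes)
  f <- vapply(seq_len(nrow(subjects)), function(i) {
    ## analyte within time, matching expand_grid row order per subject
    m <- matrix(pr[, i, ], nrow = length(times), ncol = 3,
                dimnames = list(NULL, tmdd_analytes()))
    c(t(m[, analytes, drop = FALSE]))
  }, numeric(n_obs))
  fv <- c(f)                                    # subject-major stacking
  sd_prop <- unname(sqrt(params$sigma2[out$analyte]))
  out$dv <- unname(fv * (1 + c(t(eps)) * sd_prop))
  out$pre_dose <- out$time == 0
  attr(out, "seed") <- seed
  attr(out, "design_id") <- design$id
  attr(out, "etas") <- etas
  class(out) <- c("tmdd_dataset", class(out))
  out
}

#' Write / read a dataset in NONMEM-style long format
#'
#' Serializes a simulated dataset to CSV with the conventional columns
#' `ID, TIME, DVID, DV, AMT, EVID, DOSEGRP`: one dosing record per subject
#' (`EVID = 1`, `AMT` in mg, `DVID = 0`) followed by observation records
#' (`EVID = 0`, `DVID` 1..3 indexing [tmdd_analytes()]). The round trip is
#' bit-exact for the observed values.
#'
#' @param data A `tmdd_dataset` tibble from [simulate_dataset()].
#' @param path File path.
#' @return `write_dataset_nm()` returns `path` invisibly;
#'   `read_dataset_nm()` returns a `tmdd_dataset` tibble (observation rows
#'   only, dosing records folded back into `dose_mg`).
#' @export
write_dataset_nm <- function(data, path) {
  obs <- tibble::tibble(
    ID = data$id, TIME = data$time,
    DVID = match(data$analyte, tmdd_analytes()),
    DV = data$dv, AMT = 0, EVID = 0L, DOSEGRP = data$dose_mg
  )
  dose <- obs |>
    dplyr::distinct(.data$ID, .data$DOSEGRP) |>
    dplyr::transmute(.data$ID, TIME = 0, DVID = 0L, DV = 0,
                     AMT = .data$DOSEGRP, EVID = 1L, .data$DOSEGRP)
  tab <- dplyr::arrange(dplyr::bind_rows(dose, obs),
                        .data$ID, .data$EVID != 1, .data$TIME, .data$DVID)
  ## %.17g guarantees a bit-exact double round trip
  for (col in c("TIME", "DV", "AMT", "DOSEGRP")) {
    tab[[col]] <- sprintf("%.17g", tab[[col]])
  }
  readr::write_csv(tab, path)
  invisible(path)
}

#' @rdname write_dataset_nm
#' @export
read_dataset_nm <- function(path) {
  ## base read.csv parses doubles with strtod (exact), which the fast
  ## readr parser is not guaranteed to do to the last ulp
  tab <- utils::read.csv(path)
  obs <- tab[tab$EVID == 0, ]
  out <- tibble::tibble(
    id = obs$ID, dose_mg = obs$DOSEGRP, time = obs$TIME,
    analyte = tmdd_analytes()[obs$DVID], dv = obs$DV,
    pre_dose = obs$TIME == 0
  )
  class(out) <- c("tmdd_dataset", class(out))
  out
}
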