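test_that("drug-free system sits exactly at the target turnover steady state", {
  p <- ref_params()
  r0 <- tmddesign:::r0_nm(p)

  ## derivative is zero at the steady state
  expect_equal(tmdd_rhs(c(0, 0, r0), p), c(A_depot = 0, D_tot = 0, R_tot = 0))

  ## zero dose pins the IgE analytes at baseline over the whole study span
  tr <- typical_prediction(p, dose_mg = 0, times = seq(0, 84, by = 1))
  wide <- tidyr::pivot_wider(tibble::as_tibble(tr),
                             names_from = "analyte", values_from = "value")
  expect_true(all(wide$OMA_TOT == 0))
  expect_lt(max(abs(wide$IGE_TOT - 422.82)) / 422.82, 1e-6)
  expect_lt(max(abs(wide$IGE_FREE - 422.82)) / 422.82, 1e-6)
})

test_that("right-hand side matches a fine-step Euler oracle from mid-profile", {
  p <- ref_params()
  ## state at day 5 after 150 mg, then advance 0.1 day by explicit Euler
  st <- tmddesign:::solve_blocks(p, list(list(theta = p$theta, dose_mg = 150)),
                                 times = c(5, 5.1))
  y <- st[1, 1, ]
  dt <- 1e-5
  for (i in seq_len(0.1 / dt)) y <- y + dt * tmdd_rhs(y, p)
  expect_equal(unname(y), unname(st[2, 1, ]), tolerance = 1e-4)

  ## absorption-only: positive influx proportional to depot amount
  d <- tmdd_rhs(c(100, 0, 0), p)
  expect_equal(unname(d["D_tot"]), 100 * p$theta[["ka"]] / p$theta[["V"]],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(tmdd_rhs(c(NaN, 0, 0), p), "non-finite")
})

test_that("individual predictions reduce to and scale from the typical subject", {
  p <- ref_params()
  times <- c(0, 1, 7, 14, 28, 56, 84)
  typ <- typical_prediction(p, 150, times)
  ind0 <- individual_prediction(p, eta = c(CL_OMA = 0), 150, times)
  expect_equal(ind0$value, typ$value)
  expect_error(individual_prediction(p, eta = c(V = 1), 150, times), "IIV")

  ## doubling drug clearance steepens the terminal decline of total drug
  ind2 <- individual_prediction(p, eta = c(CL_OMA = log(2)), 150, c(56, 84))
  oma <- function(tr) tr$value[tr$analyte == "OMA_TOT"]
  slope_typ <- diff(log(oma(typical_prediction(p, 150, c(56, 84))))) / 28
  slope_ind <- diff(log(oma(ind2))) / 28
  expect_lt(slope_ind, slope_typ)
})

test_that("terminal half-life is regression-stable and has the linear limit", {
  p <- ref_params()
  th <- terminal_half_life(p)
  expect_gt(attr(th, "r.squared"), 0.999)

  ## one-compartment reduction: no binding, half-life = ln2 V / CL
  lin <- linear_params()
  expect_equal(as.numeric(terminal_half_life(lin)),
               log(2) * lin$theta[["V"]] / lin$theta[["CL_OMA"]],
               tolerance = 0.01)
})

test_that("predictions are solver-tolerance robust and mass-balanced", {
  p <- ref_params()
  times <- design_catalogue("1")$sample_times
  a <- typical_prediction(p, 300, times, rtol = 1e-8, atol = 1e-10)
  b <- typical_prediction(p, 300, times, rtol = 5e-9, atol = 5e-11)
  nz <- a$value > 0
  expect_lt(max(abs(a$value[nz] - b$value[nz]) / a$value[nz]), 1e-4)

  ## 0 <= free <= total target at every time
  wide <- tidyr::pivot_wider(tibble::as_tibble(a),
                             names_from = "analyte", values_from = "value")
  expect_true(all(wide$IGE_FREE >= 0))
  expect_true(all(wide$IGE_TOT >= wide$IGE_FREE))
})

test_that("day-14 free target is strictly decreasing in dose", {
  p <- ref_params()
  doses <- c(1.5, 10, 50, 150, 277.5, 350, 450)
  free14 <- vapply(doses, function(d) {
    tr <- typical_prediction(p, d, 14)
    tr$value[tr$analyte == "IGE_FREE"]
  }, numeric(1))
  expect_true(all(diff(free14) < 0))
})
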