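test_that("fixed-effect block matches closed-form sensitivities in the linear limit", {
  ## with negligible target the total-drug profile is a linear one-compartment
  ## SC model with analytic sensitivities; with zero IIV the FO variance is
  ## diagonal and the fixed-effect block is J' V^-1 J
  p0 <- linear_params()
  p <- tmdd_params(p0$theta, p0$omega2 * 0, p0$sigma2, p0$fixed, p0$mw)
  times <- c(1, 3, 7, 14, 28, 56, 84)
  fim <- individual_fim(p, dose_mg = 150, times = times, analytes = "OMA_TOT")

  th <- p$theta
  ka <- th[["ka"]]; V <- th[["V"]]; cl <- th[["CL_OMA"]]; ke <- cl / V
  dose <- 150e6 / p$mw[["oma"]]                    # nmol
  scale <- p$mw[["oma"]] / 1000                    # ng/mL per nM
  f_fun <- function(ka, V, cl) {
    ke <- cl / V
    th[["F"]] * dose * ka / (V * (ka - ke)) * (exp(-ke * times) - exp(-ka * times)) * scale
  }
  f <- f_fun(ka, V, cl)
  ## partial derivatives of the closed form (central differences on the
  ## analytic expression, independent of the ODE machinery)
  d_ka <- (f_fun(ka * (1 + 1e-7), V, cl) - f_fun(ka * (1 - 1e-7), V, cl)) / (2e-7 * ka)
  g_cl <- (f_fun(ka, V, cl * (1 + 1e-7)) - f_fun(ka, V, cl * (1 - 1e-7))) / (2e-7 * cl)
  g_v <- (f_fun(ka, V * (1 + 1e-7), cl) - f_fun(ka, V * (1 - 1e-7), cl)) / (2e-7 * V)
  vinv <- 1 / (p$sigma2[["OMA_TOT"]] * f^2)
  expect_equal(fim["CL_OMA", "CL_OMA"], sum(g_cl^2 * vinv),
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(fim["ka", "ka"], sum(d_ka^2 * vinv),
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(fim["V", "V"], sum(g_v^2 * vinv),
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(fim["CL_OMA", "V"], sum(g_cl * g_v * vinv),
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("population FIM is additive over subjects with the D-criterion scaling law", {
  p <- ref_params()
  d <- design_catalogue("12")
  f1 <- population_fim(p, d)
  d2 <- tmdd_design("12x2", dplyr::mutate(d$groups, n_subjects = n_subjects * 2L),
                    d$sample_times, d$analytes, d$max_time)
  f2 <- population_fim(p, d2)
  expect_equal(f2$fim, 2 * f1$fim, tolerance = 1e-10)
  expect_equal(f2$log_det, f1$log_det + f1$p * log(2), tolerance = 1e-8)
  expect_equal(as.numeric(efficiency(f2, f1)), 2, tolerance = 1e-8)

  ## brute-force summation oracle: group-by-group individual FIMs
  brute <- Reduce(`+`, lapply(seq_len(nrow(d$groups)), function(g) {
    d$groups$n_subjects[g] *
      individual_fim(p, d$groups$dose_mg[g], d$sample_times, d$analytes)
  }))
  expect_equal(f1$fim, brute, tolerance = 1e-12)
})

test_that("reduced FIM has an exactly zero fixed-random cross-block", {
  p <- ref_params()
  fim <- individual_fim(p, 150, c(0, 1, 7, 28, 84))
  fixed <- tmddesign:::estimated_theta(p)
  rand <- setdiff(rownames(fim), fixed)
  expect_true(all(fim[fixed, rand] == 0))
  expect_true(isSymmetric(fim))
})

test_that("D-criterion has the determinant identities", {
  expect_equal(d_criterion(diag(5)), 0)
  set.seed(3)
  a <- crossprod(matrix(stats::rnorm(49), 7))
  expect_equal(d_criterion(3.7 * a), d_criterion(a) + 7 * log(3.7),
               tolerance = 1e-10)
  ## eigenvalue-product oracle
  expect_equal(d_criterion(a), sum(log(eigen(a, symmetric = TRUE)$values)),
               tolerance = 1e-10)
  ## singular matrix flagged, not an error
  s <- d_criterion(matrix(0, 3, 3))
  expect_identical(as.numeric(s), -Inf)
  expect_true(attr(s, "singular"))
})

test_that("efficiency is 1 against itself and restricts to the common parameters", {
  p <- ref_params()
  f1 <- population_fim(p, design_catalogue("1"))
  expect_equal(as.numeric(efficiency(f1, f1)), 1)
  f12 <- population_fim(p, design_catalogue("12"))
  e <- efficiency(f12, f1)
  expect_equal(attr(e, "p"), 13)  # sigma2 of the unmeasured analyte dropped
  expect_true(e > 0 && e < 1)
})

test_that("a pre-dose-only design is flagged singular", {
  p <- ref_params()
  d <- tmdd_design("degenerate", tibble::tibble(dose_mg = 150, n_subjects = 48),
                   sample_times = 0, max_time = 84)
  fim <- population_fim(p, d)
  expect_identical(as.numeric(fim$log_det), -Inf)
})

test_that("FIM-predicted RSE matches the closed form for a diagonal FIM", {
  p <- ref_params()
  vals <- tmddesign:::estimated_values(p)
  dvec <- seq(2, 15, length.out = length(vals))
  fake <- tmddesign:::new_tmdd_fim(diag(dvec) |>
                                     `dimnames<-`(list(names(vals), names(vals))))
  rse <- predicted_rse(fake, p)
  expect_equal(rse$rse_pct, 100 / (abs(vals) * sqrt(dvec)), ignore_attr = TRUE)
  ## solve() cross-check of the inversion route on a real FIM
  f1 <- population_fim(p, design_catalogue("12"))
  rse1 <- predicted_rse(f1, p)
  direct <- 100 * sqrt(diag(solve(f1$fim))) / abs(vals[f1$param_order])
  expect_equal(rse1$rse_pct, unname(direct), tolerance = 1e-8)
})

test_that("adding a sampling time never decreases the D-criterion", {
  p <- ref_params()
  set.seed(7)
  base_times <- c(0, 1, 7, 28, 84)
  d0 <- tmdd_design("m0", tibble::tibble(dose_mg = c(75, 300), n_subjects = 12),
                    base_times, max_time = 84)
  ld0 <- population_fim(p, d0)$log_det
  for (extra in c(0.5, 3, 14, 42, 84)) {
    d1 <- tmdd_design("m1", d0$groups, c(base_times, extra), max_time = 84)
    expect_gte(population_fim(p, d1)$log_det, ld0 - 1e-8)
  }
})

test_that("finite-difference sensitivities are step-size stable", {
  p <- ref_params()
  s1 <- tmddesign:::model_sensitivities(p, 150, c(1, 7, 28, 84), rel_step = 1e-4)
  s2 <- tmddesign:::model_sensitivities(p, 150, c(1, 7, 28, 84), rel_step = 5e-5)
  ref <- max(abs(s1$jtheta))
  expect_lt(max(abs(s1$jtheta - s2$jtheta)) / ref, 1e-3)
})
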