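test_that("simulated datasets have the design's exact record accounting", {
  p <- ref_params()
  d1 <- design_catalogue("1")
  dat <- simulate_dataset(p, d1, seed = 5)
  expect_equal(nrow(dat), 1872)
  expect_equal(nrow(dat) / length(unique(dat$id)), 39)
  ## every subject has every design time for every analyte
  counts <- dplyr::count(dat, id)
  expect_true(all(counts$n == 39))

  dat12 <- simulate_dataset(p, design_catalogue("12"), seed = 5)
  expect_equal(nrow(dat12), 480)
  expect_setequal(unique(dat12$analyte), c("OMA_TOT", "IGE_FREE"))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  p <- ref_params()
  d <- design_catalogue("12")
  a <- simulate_dataset(p, d, seed = 77)
  b <- simulate_dataset(p, d, seed = 77)
  expect_identical(a$dv, b$dv)
  c_ <- simulate_dataset(p, d, seed = 78)
  expect_false(identical(a$dv, c_$dv))
})

test_that("noise-free simulation equals the typical prediction exactly", {
  p0 <- noise_free_params()
  d <- design_catalogue("12")
  dat <- simulate_dataset(p0, d, seed = 3)
  typ <- typical_prediction(p0, 75, d$sample_times)
  sub <- dat[dat$id == 1, ]
  for (a in d$analytes) {
    ## stacked-subject and single-subject solves agree to integrator accuracy
    expect_equal(sub$dv[sub$analyte == a],
                 typ$value[typ$analyte == a], tolerance = 1e-6)
  }
  ## pre-dose drug records are structural zeros
  expect_true(all(dat$dv[dat$pre_dose & dat$analyte == "OMA_TOT"] == 0))
})

test_that("random effects have the declared log-normal distribution", {
  p <- ref_params()
  ## large-n subject pool; two cheap times keep the ODE work negligible
  big <- tmdd_design("mc", tibble::tibble(dose_mg = 150, n_subjects = 10000),
                     c(0, 1), analytes = "IGE_FREE", max_time = 84)
  dat <- simulate_dataset(p, big, seed = 123)
  etas <- attr(dat, "etas")
  for (k in colnames(etas)) {
    om <- p$omega2[[k]]
    ## sample log-variance within 3 MC standard errors of omega2
    se <- om * sqrt(2 / (nrow(etas) - 1))
    expect_lt(abs(stats::var(etas[, k]) - om), 3 * se)
    ## Kolmogorov-Smirnov non-rejection at alpha = 0.01
    expect_gt(stats::ks.test(etas[, k], "pnorm", 0, sqrt(om))$p.value, 0.01)
  }
})

test_that("NONMEM-style CSV round trip is bit-exact", {
  p <- ref_params()
  dat <- simulate_dataset(p, design_catalogue("12"), seed = 9)
  tmp <- tempfile(fileext = ".csv")
  write_dataset_nm(dat, tmp)
  back <- read_dataset_nm(tmp)
  expect_identical(back$dv, dat$dv)
  expect_equal(back$id, dat$id)
  expect_equal(back$time, dat$time)
  expect_equal(back$analyte, dat$analyte)
  expect_equal(back$dose_mg, dat$dose_mg)
})
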