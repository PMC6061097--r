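test_that("prediction-interval percentiles match a sort-and-interpolate oracle", {
  p <- ref_params()
  ## hand-made parameter vectors: scaled clearances give ordered trajectories
  sets <- lapply(c(0.7, 0.85, 1, 1.15, 1.3, 1.5, 0.6), function(s) {
    th <- p$theta
    th["CL_IGE"] <- th["CL_IGE"] * s
    th
  })
  times <- c(1, 7, 14, 28)
  ppa <- population_prediction_area(sets, params = p, dose_mg = 150,
                                    times = times)
  ## oracle: type-7 interpolation computed by hand from the sorted values
  pred <- sapply(sets, function(th) {
    blocks <- list(list(theta = th, dose_mg = 150))
    tmddesign:::predict_blocks(p, blocks, times)[, 1, "IGE_FREE"]
  })
  type7 <- function(x, prob) {
    xs <- sort(x)
    h <- (length(xs) - 1) * prob
    lo <- floor(h)
    xs[lo + 1] + (h - lo) * (xs[min(lo + 2, length(xs))] - xs[lo + 1])
  }
  for (i in seq_along(times)) {
    expect_equal(ppa$lower[i], type7(pred[i, ], 0.025), tolerance = 1e-6)
    expect_equal(ppa$upper[i], type7(pred[i, ], 0.975), tolerance = 1e-6)
  }
  expect_equal(attr(ppa, "ppa"), sum(ppa$upper - ppa$lower))

  ## identical vectors: zero-width area; reordering leaves the PPA unchanged
  same <- population_prediction_area(rep(list(p$theta), 3), params = p,
                                     times = times)
  expect_equal(attr(same, "ppa"), 0)
  ppa_rev <- population_prediction_area(rev(sets), params = p, dose_mg = 150,
                                        times = times)
  expect_equal(attr(ppa_rev, "ppa"), attr(ppa, "ppa"))
  expect_equal(ppa_ratio(ppa, ppa), 1)

  ## a vector outside the envelope can only widen the area
  wide <- c(sets, list({th <- p$theta; th["CL_IGE"] <- th["CL_IGE"] * 3; th}))
  ppa_wide <- population_prediction_area(wide, params = p, dose_mg = 150,
                                         times = times)
  expect_gte(attr(ppa_wide, "ppa"), attr(ppa, "ppa"))
})

test_that("true dose agrees with a grid-scan oracle and has the small-reduction limit", {
  p <- ref_params()
  td <- true_dose(p, tol = 0.05)
  ## independent scan of the dose axis at 0.1 mg resolution
  doses <- seq(td - 5, td + 5, by = 0.1)
  free14 <- vapply(doses, function(d) {
    tr <- typical_prediction(p, d, 14)
    tr$value[tr$analyte == "IGE_FREE"]
  }, numeric(1))
  target <- 0.05 * p$theta[["R0"]]
  cross <- doses[which(free14 < target)[1]]
  expect_lt(abs(td - cross), 0.2)

  ## a tiny required reduction needs only a tiny dose
  expect_lt(true_dose(p, reduction = 0.02, time = 14), 5)
  expect_error(true_dose(p, reduction = 0.99999, interval = c(0, 10)),
               "not bracketed")
})

test_that("decision rule: truth-only vectors make no incorrect decision", {
  p <- ref_params()
  dec <- decision_probability(list(p$theta, p$theta), params = p)
  expect_equal(dec$p_incorrect, 0)
  expect_equal(dim(dec$incorrect), c(2, 300))
  expect_equal(dec$doses, seq(1.5, 450, by = 1.5))
})

test_that("decision counting matches an independent re-application of the rule", {
  p <- ref_params()
  ## two vectors with shifted dose-response (stronger/weaker apparent potency)
  sets <- lapply(c(0.8, 1.25), function(s) {
    th <- p$theta
    th["KD"] <- th["KD"] * s
    th
  })
  doses <- seq(150, 400, by = 12.5)
  dec <- decision_probability(sets, params = p, doses = doses)
  ## oracle: loop the public prediction API and apply the written rule
  for (v in seq_along(sets)) {
    for (k in seq_along(doses)) {
      blocks <- list(list(theta = sets[[v]], dose_mg = doses[k]))
      pred <- tmddesign:::predict_blocks(p, blocks, 14)[1, 1, "IGE_FREE"]
      bad <- (doses[k] > dec$true_dose && pred > dec$threshold) ||
        (doses[k] < dec$true_dose && pred < dec$threshold)
      expect_identical(unname(dec$incorrect[v, k]), bad)
    }
  }
  expect_equal(dec$p_incorrect, mean(dec$incorrect))
})
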