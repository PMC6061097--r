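test_that("fixed effects are recovered from noise-free data", {
  p0 <- noise_free_params(eps = 1e-8)
  dat <- simulate_dataset(p0, design_catalogue("1"), seed = 7)
  fit <- suppressWarnings(fit_dataset(dat, init = p0))
  th <- intersect(fit$labels, names(p0$theta))
  expect_lt(max(abs(fit$estimate[th] / p0$theta[th] - 1)), 1e-3)
})

test_that("FO objective prefers the truth over perturbed parameters on rich data", {
  p <- ref_params()
  d1 <- design_catalogue("1")
  big <- tmdd_design("big", dplyr::mutate(d1$groups, n_subjects = 125L),
                     d1$sample_times, d1$analytes, 84)
  dat <- simulate_dataset(p, big, seed = 31)
  prep <- tmddesign:::prepare_fit_data(dat)
  labels <- tmddesign:::estimated_labels(p, prep$analytes)
  x_true <- log(tmddesign:::estimated_values(p, prep$analytes)[labels])
  obj <- function(x) tmddesign:::fo_objective(x, prep, p, labels, 1e-6, 1e-8)
  o_true <- obj(x_true)
  expect_lt(o_true, obj(x_true + log(1.2)))
  expect_lt(o_true, obj(x_true - log(1.2)))
})

test_that("SSE is deterministic given a seed and records convergence", {
  p <- ref_params()
  d <- design_catalogue("12")
  s1 <- suppressWarnings(run_sse(p, d, n_reps = 2, seed = 5, maxit = 40))
  s2 <- suppressWarnings(run_sse(p, d, n_reps = 2, seed = 5, maxit = 40))
  expect_identical(s1$estimates, s2$estimates)
  expect_equal(s1$n_requested, 2)
  expect_length(s1$seeds, 2)
  expect_lte(s1$n_converged, 2)
})

test_that("empirical RSE matches its sampling-distribution definition", {
  p <- ref_params()
  labels <- tmddesign:::estimated_labels(p)
  truth <- tmddesign:::estimated_values(p)
  make_sse <- function(est_mat) {
    est <- tibble::as_tibble(est_mat)
    est <- dplyr::bind_cols(tibble::tibble(rep = seq_len(nrow(est)),
                                           converged = TRUE,
                                           objective = 0), est)
    structure(list(design_id = "toy", estimates = est, true_params = p,
                   n_requested = nrow(est), n_converged = nrow(est),
                   seeds = seq_len(nrow(est))),
              class = "tmdd_sse")
  }
  ## identical replicates: all RSE zero
  m0 <- matrix(rep(truth, each = 5), 5, dimnames = list(NULL, labels))
  rse0 <- empirical_rse(make_sse(m0))
  expect_true(all(rse0$rse_pct == 0))
  expect_equal(attr(rse0, "average"), 0)

  ## N(mu, (0.2 mu)^2) draws converge to 20% RSE
  set.seed(42)
  n <- 4000
  m <- vapply(truth, function(mu) stats::rnorm(n, mu, 0.2 * abs(mu)),
              numeric(n))
  colnames(m) <- labels
  rse <- empirical_rse(make_sse(m))
  expect_equal(rse$rse_pct, rep(20, length(labels)), tolerance = 0.05)

  expect_error(empirical_rse(make_sse(m0[1, , drop = FALSE])), "at least 2")
})
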