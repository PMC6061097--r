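## shared fixtures, built in code

ref_params <- function() omalizumab_params()

## parameter set with IIV and residual noise switched off (deterministic data)
noise_free_params <- function(eps = 0) {
  p <- ref_params()
  tmdd_params(p$theta, p$omega2 * 0 + eps, p$sigma2 * 0 + eps,
              fixed = p$fixed, mw = p$mw)
}

## a linear one-compartment limit of the model: negligible target, weak binding
linear_params <- function() {
  p <- ref_params()
  th <- p$theta
  th["KD"] <- 1e6
  th["R0"] <- 1e-6
  tmdd_params(th, p$omega2, p$sigma2, fixed = p$fixed, mw = p$mw)
}

## cache expensive SSE runs so several test files can share them
.sse_cache <- new.env(parent = emptyenv())
cached_sse <- function(design_id, n_reps, seed = 20240601) {
  key <- paste(design_id, n_reps, seed, sep = "_")
  if (is.null(.sse_cache[[key]])) {
    .sse_cache[[key]] <- suppressWarnings(
      run_sse(ref_params(), design_catalogue(design_id),
              n_reps = n_reps, seed = seed)
    )
  }
  .sse_cache[[key]]
}
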