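#' Candidate sampling-time grid
#'
#' Discretizes the allowed sampling window `[0, max_time]` into
#' `grid_size + 1` equally spaced candidate times, the search space of the
#' line-search optimizer. With `max_time = 84` and `grid_size = 84` a
#' sampling time can be selected every day of the reference study span.
#'
#' @param max_time End of the sampling window (days, > 0).
#' @param grid_size Number of grid intervals (>= 1).
#' @return Numeric vector of `grid_size + 1` candidate days.
#' @examples
#' make_time_grid(84, 84)
#' make_time_grid(28, 84)[c(2, 24)] # 1/3-day spacing
#' @export
make_time_grid <- function(max_time, grid_size) {
  stopifnot(max_time > 0, grid_size >= 1)
  seq(0, max_time, length.out = grid_size + 1)
}

## Deterministic cyclic coordinate search over a discretized candidate set.
## `x` and `candidates` are indices (or values) understood by `crit_fn`,
## which must return a scalar criterion to MAXIMIZE. Tie-breaking: within
## `rel_tol` relative of the best, keep the current coordinate if it ties,
## otherwise take the earliest candidate. No randomness: identical inputs
## give identical output.
ls_search <- function(x, candidates, crit_fn, max_cycles = 50, rel_tol = 1e-10) {
  cur <- x[order(x)]
  ld <- crit_fn(cur)
  if (!is.finite(ld)) stop("criterion is singular at the initial design")
  trace <- ld
  n_cycles <- 0
  for (cycle in seq_len(max_cycles)) {
    n_cycles <- cycle
    improved <- FALSE
    for (i in seq_along(cur)) {
      lds <- vapply(candidates, function(cand) {
        trial <- cur; trial[i] <- cand
        crit_fn(trial)
      }, numeric(1))
      best <- max(c(lds, ld))
      tol <- rel_tol * abs(best)
      if (ld >= best - tol) next      # current coordinate already ties the best
      j <- which(lds >= best - tol)[1]
      cur[i] <- candidates[j]
      ld <- lds[j]
      trace <- c(trace, ld)
      improved <- TRUE
    }
    if (!improved) break
  }
  list(x = cur, criterion = ld, trace = trace, n_cycles = n_cycles)
}

#' Optimize sampling times by discretized line search
#'
#' Cyclic coordinate (line-search) optimization of a design's sampling times
#' under the D-criterion: each time coordinate in turn is moved to the best
#' of `grid_size + 1` equally spaced candidates in `[0, max_time]`, and
#' cycles repeat until a full pass yields no improvement. Clustering
#' (duplicate times) is allowed; the pre-dose time is optimizable like any
#' other coordinate. The search is deterministic.
#'
#' Model sensitivities are pre-computed once per dose group on the candidate
#' grid, so each of the up to `(grid_size + 1) * length(times)` evaluations
#' per cycle is pure linear algebra.
#'
#' @param design A [tmdd_design]; its `max_time` bounds the grid.
#' @param params A [tmdd_params] object.
#' @param grid_size Number of grid intervals (default 84).
#' @param max_cycles Cycle cap (default 50).
#' @return An object of class `tmdd_ls`: list with `initial_design`,
#'   `optimized_design`, `criterion_trace` (tibble of log-determinants per
#'   accepted move), and `n_cycles`.
#' @examples
#' \donttest{
#' res <- optimize_times(design_catalogue("4"), omalizumab_params())
#' res$optimized_design$sample_times
#' }
#' @export
optimize_times <- function(design, params, grid_size = 84, max_cycles = 50) {
  stopifnot(inherits(design, "tmdd_design"), inherits(params, "tmdd_params"))
  grid <- make_time_grid(design$max_time, grid_size)
  ut <- sort(unique(c(grid, design$sample_times)))
  sens <- lapply(design$groups$dose_mg, function(d) {
    model_sensitivities(params, d, ut)
  })
  crit_fn <- function(idx) {
    fim <- NULL
    for (g in seq_along(sens)) {
      contrib <- tryCatch(
        assemble_group_fim(sens[[g]], idx, design$analytes, params,
                           design$groups$n_subjects[g]),
        error = function(e) NULL)
      if (is.null(contrib)) return(-Inf)
      fim <- if (is.null(fim)) contrib else fim + contrib
    }
    d_criterion(fim)
  }
  res <- ls_search(match(design$sample_times, ut), match(grid, ut), crit_fn,
                   max_cycles = max_cycles)
  opt <- tmdd_design(paste0(design$id, "opt"), design$groups, ut[res$x],
                     design$analytes, design$max_time,
                     paste("line-search optimum of design", design$id))
  structure(
    list(initial_design = design, optimized_design = opt,
         criterion_trace = tibble::tibble(step = seq_along(res$trace) - 1,
                                          log_det = res$trace),
         n_cycles = res$n_cycles),
    class = "tmdd_ls"
  )
}

#' @export
print.tmdd_ls <- function(x, ...) {
  tr <- x$criterion_trace$log_det
  cat("<tmdd_ls> design", x$initial_design$id, "|", x$n_cycles, "cycles |",
      length(tr) - 1, "accepted moves\n")
  cat("  log det:", format(tr[1], digits = 8), "->",
      format(tr[length(tr)], digits = 8), "\n")
  cat("  times:", paste(round(x$optimized_design$sample_times, 3), collapse = ", "), "\n")
  invisible(x)
}
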