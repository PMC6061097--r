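#' Construct a trial design
#'
#' A design is a set of dose groups, one shared vector of sampling times
#' (shared across analytes and dose groups; duplicate times are permitted,
#' since clustering of samples is allowed during optimization), the set of
#' measured analytes, and the upper bound of the sampling window used when
#' times are optimized.
#'
#' @param id Design label, e.g. `"1"` or `"4O"`.
#' @param groups Data frame with columns `dose_mg` (> 0) and `n_subjects`
#'   (>= 1), one row per dose group.
#' @param sample_times Sampling days, within `[0, max_time]`.
#' @param analytes Non-empty subset of [tmdd_analytes()].
#' @param max_time Upper bound (days) of the allowed sampling window.
#' @param description Optional free-text description.
#' @return An object of class `tmdd_design`.
#' @export
tmdd_design <- function(id, groups, sample_times, analytes = tmdd_analytes(),
                        max_time = max(sample_times), description = "") {
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("dose_mg", "n_subjects") %in% names(groups)))
  if (any(groups$dose_mg <= 0) || any(groups$n_subjects < 1)) {
    stop("dose_mg must be positive and n_subjects >= 1")
  }
  if (length(analytes) == 0 || !all(analytes %in% tmdd_analytes())) {
    stop("analytes must be a non-empty subset of ",
         paste(tmdd_analytes(), collapse = ", "))
  }
  if (any(sample_times < 0) || any(sample_times > max_time)) {
    stop("sample_times must lie within [0, max_time]")
  }
  structure(
    list(id = as.character(id), groups = groups,
         sample_times = sort(as.numeric(sample_times)),
         analytes = intersect(tmdd_analytes(), analytes),
         max_time = max_time, description = description),
    class = "tmdd_design"
  )
}

#' Summary counts of a design
#'
#' @param design A [tmdd_design] object.
#' @return A tibble with `obs_per_individual` (number of sampling times
#'   times number of analytes) and `total_samples` (times total subjects).
#' @examples
#' design_summary(design_catalogue("1"))
#' @export
design_summary <- function(design) {
  stopifnot(inherits(design, "tmdd_design"))
  obs <- length(design$sample_times) * length(design$analytes)
  tibble::tibble(
    id = design$id,
    obs_per_individual = obs,
    total_samples = obs * sum(design$groups$n_subjects)
  )
}

#' @export
print.tmdd_design <- function(x, ...) {
  cat("<tmdd_design>", x$id, if (nzchar(x$description)) paste0("- ", x$description), "\n")
  cat("  groups:", paste(sprintf("%g mg x %d", x$groups$dose_mg, x$groups$n_subjects),
                         collapse = ", "), "\n")
  cat("  times (d):", paste(x$sample_times, collapse = ", "), "\n")
  cat("  analytes:", paste(x$analytes, collapse = ", "),
      " | max_time:", x$max_time, "d\n")
  invisible(x)
}

## shared building blocks of the catalogue
.ref_times <- c(0, 0.5, 1, 2, 4, 7, 10, 14, 28, 42, 56, 70, 84)
.four_groups <- function() tibble::tibble(dose_mg = c(75, 150, 300, 375), n_subjects = 12L)
## design 5 removes two dose groups and their subjects: 2 x 12 = 24 subjects,
## matching the published total of 936 = 24 x 39 samples
.two_groups <- function() tibble::tibble(dose_mg = c(75, 150), n_subjects = 12L)

.catalogue_spec <- function() {
  A <- tmdd_analytes()
  list(
    ## initial designs
    list("1",  .four_groups(), .ref_times, A, 84, "Reference design"),
    list("2",  .four_groups(), seq(0, 2, by = 0.25), A, 2, "Sampling for 2 days"),
    list("3",  .four_groups(), c(0, 0.5, 1, 2, 4, 6, 8, 10, 14), A, 14, "Sampling for 14 days"),
    list("4",  .four_groups(), c(0, 0.5, 1, 2, 4, 7, 10, 14, 28), A, 28, "Sampling for 28 days"),
    list("5",  .two_groups(), .ref_times, A, 84, "Two dose groups removed"),
    list("6",  .four_groups(), c(0, 0.5, 1, 2, 4, 7, 10, 14, 28), A, 84,
         "Minus 4 samples per analyte (optimization window open to day 84)"),
    list("7",  .four_groups(), c(0, 0.5, 1, 4, 7, 28, 84), A, 84, "Minus 6 samples per analyte"),
    list("8",  .four_groups(), c(0, 0.5, 7, 14, 84), A, 84, "Minus 8 samples per analyte"),
    list("9",  .four_groups(), .ref_times, c("OMA_TOT", "IGE_FREE"), 84, "No total IgE sampling"),
    list("10", .four_groups(), .ref_times, c("OMA_TOT", "IGE_TOT"), 84, "No free IgE sampling"),
    list("11", .four_groups(), .ref_times, c("IGE_FREE", "IGE_TOT"), 84, "No total drug sampling"),
    list("12", .four_groups(), c(0, 0.5, 1, 4, 84), c("OMA_TOT", "IGE_FREE"), 84,
         "No total IgE, minus 8 samples per remaining analyte"),
    ## optimized variants: published line-search solutions, used as fixed inputs
    list("1O",  .four_groups(), c(0, 0, 0.5, 1, 11, 11, 11, 11, 11, 11, 46, 71, 84), A, 84, "Design 1, optimized"),
    list("2O",  .four_groups(), c(0, 0.14, 0.14, 0.81, 0.81, 2, 2, 2, 2), A, 2, "Design 2, optimized"),
    list("3O",  .four_groups(), c(0, 0.17, 4.89, 5.06, 5.23, 14, 14, 14, 14), A, 14, "Design 3, optimized"),
    list("4O",  .four_groups(), c(0, 0.33, 7.67, 7.67, 7.67, 7.67, 28, 28, 28), A, 28, "Design 4, optimized"),
    list("5O",  .two_groups(), c(0, 0, 0.5, 1, 10, 10, 10, 10, 10, 40, 40, 72, 84), A, 84, "Design 5, optimized"),
    list("6O",  .four_groups(), c(0, 11, 11, 11, 11, 24, 24, 47, 83), A, 84, "Design 6, optimized"),
    list("7O",  .four_groups(), c(0, 1, 11, 11, 11, 46, 83), A, 84, "Design 7, optimized"),
    list("8O",  .four_groups(), c(0, 0.5, 12, 12, 72), A, 84, "Design 8, optimized"),
    list("9O",  .four_groups(), c(0, 0, 0.5, 1, 1, 11, 11, 11, 11, 36, 40, 74, 84),
         c("OMA_TOT", "IGE_FREE"), 84, "Design 9, optimized"),
    list("10O", .four_groups(), c(0, 0, 0.5, 1, 11, 11, 11, 11, 46, 46, 73, 84, 84),
         c("OMA_TOT", "IGE_TOT"), 84, "Design 10, optimized"),
    list("11O", .four_groups(), c(0, 0, 0.5, 1, 1, 12, 13, 13, 13, 56, 72, 72, 84),
         c("IGE_FREE", "IGE_TOT"), 84, "Design 11, optimized"),
    list("12O", .four_groups(), c(0, 0.5, 10, 39, 83), c("OMA_TOT", "IGE_FREE"), 84,
         "Design 12, optimized")
  )
}

#' The catalogue of evaluated trial designs
#'
#' Twelve single-dose subcutaneous designs derived from a rich reference
#' study (48 subjects in four dose groups of 75/150/300/375 mg, 13 sampling
#' days over 0--84 days, three analytes per sample) by shortening the
#' sampling duration, removing dose groups, removing samples or omitting an
#' analyte, plus their line-search-optimized variants (`"1O"` ... `"12O"`,
#' whose published optimized times are shipped as fixed inputs).
#'
#' @param id Optional design label (`"1"`..`"12"`, `"1O"`..`"12O"`). When
#'   omitted, a tibble summarizing the whole catalogue is returned.
#' @return A [tmdd_design] for a single `id`, otherwise a summary tibble.
#' @examples
#' design_catalogue()
#' design_catalogue("4O")
#' @export
design_catalogue <- function(id = NULL) {
  specs <- .catalogue_spec()
  designs <- lapply(specs, function(s) {
    tmdd_design(s[[1]], s[[2]], s[[3]], s[[4]], s[[5]], s[[6]])
  })
  names(designs) <- vapply(designs, `[[`, "", "id")
  if (!is.null(id)) {
    id <- as.character(id)
    if (!id %in% names(designs)) stop("unknown design id: ", id)
    return(designs[[id]])
  }
  purrr::map_dfr(designs, function(d) {
    dplyr::bind_cols(
      tibble::tibble(id = d$id, description = d$description,
                     n_groups = nrow(d$groups),
                     n_subjects = sum(d$groups$n_subjects),
                     n_times = length(d$sample_times),
                     analytes = paste(d$analytes, collapse = ";"),
                     max_time = d$max_time),
      design_summary(d)[, c("obs_per_individual", "total_samples")]
    )
  })
}

#' Read / write designs as CSV
#'
#' One row per design with semicolon-separated list columns, so that a
#' catalogue can be exchanged as a plain-text table.
#'
#' @param designs A [tmdd_design] or list of them.
#' @param path File path.
#' @return `write_designs()` returns `path` invisibly; `read_designs()`
#'   returns a named list of [tmdd_design] objects.
#' @export
write_designs <- function(designs, path) {
  if (inherits(designs, "tmdd_design")) designs <- list(designs)
  tab <- purrr::map_dfr(designs, function(d) {
    tibble::tibble(
      id = d$id,
      doses_mg = paste(d$groups$dose_mg, collapse = ";"),
      n_subjects = paste(d$groups$n_subjects, collapse = ";"),
      sample_times = paste(d$sample_times, collapse = ";"),
      analytes = paste(d$analytes, collapse = ";"),
      max_time = d$max_time,
      description = d$description
    )
  })
  readr::write_csv(tab, path)
  invisible(path)
}

#' @rdname write_designs
#' @export
read_designs <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  out <- purrr::pmap(tab, function(id, doses_mg, n_subjects, sample_times,
                                   analytes, max_time, description) {
    tmdd_design(
      id,
      tibble::tibble(dose_mg = as.numeric(strsplit(doses_mg, ";")[[1]]),
                     n_subjects = as.integer(strsplit(n_subjects, ";")[[1]])),
      as.numeric(strsplit(sample_times, ";")[[1]]),
      strsplit(analytes, ";")[[1]], max_time, description
    )
  })
  names(out) <- tab$id
  out
}
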