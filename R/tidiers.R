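#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a synthetic cohort
#'
#' Returns the cohort's observation table (the long record tibble after any
#' missingness injection).
#'
#' @param x A `nc_cohort` from [simulate_cohort()].
#' @param ... Unused.
#' @return Long record tibble.
#' @method tidy nc_cohort
#' @export
tidy.nc_cohort <- function(x, ...) {
  x$observations
}

#' Summarise a synthetic cohort in one row
#'
#' @param x A `nc_cohort` from [simulate_cohort()].
#' @param ... Unused.
#' @return One-row tibble: `n_patients`, `n_channels`, `duration`,
#'   `n_planted_edges`, `missing_fraction`, `seed`.
#' @method glance nc_cohort
#' @export
glance.nc_cohort <- function(x, ...) {
  tibble(
    n_patients = x$config$n_patients,
    n_channels = nrow(x$config$channels),
    duration = x$config$duration,
    n_planted_edges = if (is.null(x$truth$edges)) 0L else nrow(x$truth$edges),
    missing_fraction = mean(is.na(x$observations$value)),
    seed = x$config$seed
  )
}

#' Tidy a phenotyping result
#'
#' @param x A `nc_phenotype` from [gap_kmeans()].
#' @param ... Unused.
#' @return The cluster-assignment tibble (`patient_id`, `cluster`).
#' @method tidy nc_phenotype
#' @export
tidy.nc_phenotype <- function(x, ...) {
  x$assignments
}

#' Summarise a phenotyping result in one row
#'
#' @param x A `nc_phenotype` from [gap_kmeans()].
#' @param ... Unused.
#' @return One-row tibble: chosen `k`, `n_patients`, `n_dropped`,
#'   `max_gap`.
#' @method glance nc_phenotype
#' @export
glance.nc_phenotype <- function(x, ...) {
  tibble(
    k = x$k,
    n_patients = nrow(x$assignments),
    n_dropped = length(x$dropped),
    max_gap = max(x$gap_curve$gap)
  )
}

#' @export
print.nc_cohort <- function(x, ...) {
  g <- glance.nc_cohort(x)
  cat(sprintf(
    "synthetic cohort: %d patient(s) x %d channel(s), %d minutes each\n",
    g$n_patients, g$n_channels, g$duration
  ))
  cat(sprintf(
    "  planted edges: %d; missing fraction: %.3f; seed: %d\n",
    g$n_planted_edges, g$missing_fraction, g$seed
  ))
  invisible(x)
}
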