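# Internal helpers shared across modules.

#' @importFrom rlang .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Provenance codes used in the `status` column of record tibbles.
.nc_status_levels <- c(
  "observed", "imputed_f", "imputed_lknn", "imputed_combined",
  "derived", "missing"
)

# Deterministic per-patient seed derived from a cohort seed. Linear
# congruential mix modulo the Mersenne prime 2^31 - 1; stable across
# platforms and documented as the package's seed-derivation scheme.
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(index) * 16807
  as.integer(s %% m)
}

# Validate the canonical long record tibble.
check_record <- function(df, arg = "data") {
  needed <- c("patient_id", "variable", "minute", "value", "status")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop(sprintf(
      "`%s` must be a record tibble with columns %s (missing: %s)",
      arg, paste(needed, collapse = ", "), paste(miss, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

# Pivot a single patient's record tibble to minute x variable matrices.
# Minutes are completed to a full contiguous grid spanning the observed range.
record_matrices <- function(df) {
  stopifnot(length(unique(df$patient_id)) == 1L)
  minutes <- seq(min(df$minute), max(df$minute))
  vars <- sort(unique(df$variable))
  values <- matrix(NA_real_, length(minutes), length(vars),
    dimnames = list(NULL, vars)
  )
  status <- matrix("missing", length(minutes), length(vars),
    dimnames = list(NULL, vars)
  )
  i <- match(df$minute, minutes)
  j <- match(df$variable, vars)
  values[cbind(i, j)] <- df$value
  status[cbind(i, j)] <- df$status
  list(
    patient_id = df$patient_id[[1L]], minutes = minutes,
    values = values, status = status
  )
}

# Inverse of record_matrices().
matrices_record <- function(m) {
  vars <- colnames(m$values)
  tibble(
    patient_id = m$patient_id,
    variable = rep(vars, each = length(m$minutes)),
    minute = rep(m$minutes, times = length(vars)),
    value = as.vector(m$values),
    status = as.vector(m$status)
  )
}

# Maximal runs of TRUE in a logical vector -> tibble(start, length).
# Starts are 1-based indices into the vector.
true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  tibble(start = starts[keep], length = r$lengths[keep])
}
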