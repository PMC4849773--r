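#' Average raw observations onto a shared minute grid
#'
#' Collects raw timestamped observations into minute bins: each grid minute
#' holds the arithmetic mean of the observations whose timestamp falls in
#' `[minute, minute + 1)`. Minutes with no observation for a channel are
#' missing. The output grid is the full contiguous minute range spanned by
#' each patient's observations, shared across that patient's channels. The
#' operation is idempotent on data already at minute resolution.
#'
#' @param obs Tibble of raw observations with columns `patient_id`,
#'   `variable`, `timestamp` (seconds; numeric) and `value`.
#' @param specs Optional spec tibble; when supplied, observations of unknown
#'   variables raise a schema error.
#' @return Long record tibble (`patient_id`, `variable`, `minute`, `value`,
#'   `status`), `status` `"observed"` or `"missing"`.
#' @export
minute_average <- function(obs, specs = NULL) {
  needed <- c("patient_id", "variable", "timestamp", "value")
  stopifnot(all(needed %in% names(obs)))
  if (!is.null(specs)) {
    unknown <- setdiff(unique(obs$variable), specs$variable)
    if (length(unknown) > 0L) {
      stop("observations of unknown variable(s): ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
  }
  averaged <- obs |>
    dplyr::mutate(minute = as.integer(floor(.data$timestamp / 60))) |>
    dplyr::group_by(.data$patient_id, .data$variable, .data$minute) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  # complete each patient's grid across its channels
  grid <- averaged |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      lo = min(.data$minute), hi = max(.data$minute),
      .groups = "drop"
    )
  full <- grid |>
    dplyr::rowwise() |>
    dplyr::reframe(
      patient_id = .data$patient_id,
      minute = seq(.data$lo, .data$hi)
    ) |>
    dplyr::inner_join(
      dplyr::distinct(averaged, .data$patient_id, .data$variable),
      by = "patient_id", relationship = "many-to-many"
    )
  full |>
    dplyr::left_join(averaged, by = c("patient_id", "variable", "minute")) |>
    dplyr::mutate(status = dplyr::if_else(is.na(.data$value), "missing", "observed")) |>
    dplyr::select("patient_id", "variable", "minute", "value", "status") |>
    dplyr::arrange(.data$patient_id, .data$variable, .data$minute)
}

#' Remove physiologically implausible values
#'
#' Values outside a channel's hard plausibility bounds are treated as monitor
#' artifact and set to missing. In-bounds values are never altered. Removal
#' counts per channel are reported via `message()`.
#'
#' @param data Long record tibble.
#' @param specs Spec tibble covering all channels in `data`.
#' @param quiet Suppress the per-channel removal message.
#' @return The record tibble with implausible entries set missing.
#' @export
remove_implausible <- function(data, specs = variable_specs(), quiet = FALSE) {
  check_record(data)
  unknown <- setdiff(unique(data$variable), specs$variable)
  if (length(unknown) > 0L) {
    stop("no plausibility bounds for: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  sp <- specs[match(data$variable, specs$variable), ]
  bad <- !is.na(data$value) &
    (data$value < sp$plausibility_low | data$value > sp$plausibility_high)
  if (!quiet && any(bad)) {
    counts <- table(data$variable[bad])
    message(
      "removed implausible values: ",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")
    )
  }
  data$value[bad] <- NA_real_
  data$status[bad] <- "missing"
  data
}

#' Derive cerebral perfusion pressure
#'
#' Adds a CPP channel computed minute-by-minute as mean arterial pressure
#' minus intracranial pressure (CPP = MAP - ICP). CPP is missing wherever
#' either parent is missing. Provenance is `"derived"` when both parents are
#' observed and `"derived_imputed"` when either parent was itself imputed.
#' Patients lacking a MAP or ICP channel (not all patients receive a
#' parenchymal ICP monitor) are left unchanged with a warning.
#'
#' @param data Long record tibble.
#' @return The record tibble with a CPP channel appended per patient.
#' @export
derive_cpp <- function(data) {
  check_record(data)
  per_patient <- split(data, data$patient_id)
  out <- lapply(per_patient, function(pdat) {
    have <- unique(pdat$variable[!is.na(pdat$value)])
    if (!all(c("MAP", "ICP") %in% have)) {
      warning(
        "patient ", pdat$patient_id[[1]],
        ": MAP or ICP absent; CPP not derived",
        call. = FALSE
      )
      return(pdat)
    }
    if ("CPP" %in% pdat$variable) {
      warning(
        "patient ", pdat$patient_id[[1]],
        ": CPP already present; not rederived",
        call. = FALSE
      )
      return(pdat)
    }
    map <- pdat[pdat$variable == "MAP", ]
    icp <- pdat[pdat$variable == "ICP", ]
    j <- dplyr::inner_join(
      dplyr::select(map,
        "patient_id", "minute",
        map_value = "value", map_status = "status"
      ),
      dplyr::select(icp, "minute", icp_value = "value", icp_status = "status"),
      by = "minute"
    )
    cpp <- j |>
      dplyr::transmute(
        patient_id = .data$patient_id,
        variable = "CPP",
        minute = .data$minute,
        value = .data$map_value - .data$icp_value,
        status = dplyr::case_when(
          is.na(.data$map_value) | is.na(.data$icp_value) ~ "missing",
          .data$map_status == "observed" & .data$icp_status == "observed" ~ "derived",
          TRUE ~ "derived_imputed"
        )
      )
    extra <- c("phase", "state", "binning")
    for (col in intersect(extra, names(pdat))) cpp[[col]] <- NA
    dplyr::bind_rows(pdat, cpp)
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$patient_id, .data$variable, .data$minute)
}

#' Split a record into post-bleed phases
#'
#' Labels every minute with its analysis phase relative to the bleed: phase 1
#' covers post-bleed days 0--3 (`[bleed, bleed + 96 h)`), phase 2 days 4--7
#' (`[bleed + 96 h, bleed + 192 h)`). Boundaries are half-open, so the minute
#' exactly 96 h after the bleed belongs to phase 2. Minutes outside both
#' phases are dropped. The bleed may precede the start of monitoring
#' (monitoring typically starts days after the bleed).
#'
#' @param data Long record tibble.
#' @param bleed_minute Minute index of the bleed on the record's grid, either
#'   a single value or a named vector by `patient_id`. May be negative.
#' @return The record tibble restricted to the two phases, with an integer
#'   `phase` column.
#' @export
split_phases <- function(data, bleed_minute = 0) {
  check_record(data)
  b <- if (is.null(names(bleed_minute))) {
    rep(bleed_minute[[1]], nrow(data))
  } else {
    unname(bleed_minute[data$patient_id])
  }
  rel <- data$minute - b
  phase <- dplyr::case_when(
    rel >= 0 & rel < 96 * 60 ~ 1L,
    rel >= 96 * 60 & rel < 192 * 60 ~ 2L,
    TRUE ~ NA_integer_
  )
  out <- data[!is.na(phase), , drop = FALSE]
  out$phase <- phase[!is.na(phase)]
  if (nrow(out) == 0L) {
    warning("record lies entirely outside both phases", call. = FALSE)
  }
  out
}

#' Per-patient data-characteristics profile
#'
#' For every patient, channel (and phase, when present) computes the three
#' descriptive metrics used to profile monitoring data quality: the standard
#' deviation of observed values as a percent of their mean, the percent of
#' grid minutes with an observed value, and a KPSS level-stationarity test
#' (nonstationary when its p-value is at or below 0.01). Channels observed
#' for fewer than `min_minutes` minutes get `NA` metrics — too unstable to
#' report.
#'
#' @param data Long record tibble (optionally phase-labelled).
#' @param min_minutes Minimum observed minutes for metrics to be reported.
#' @return Tibble with one row per patient x channel (x phase): `n_observed`,
#'   `sd_percent`, `availability_percent`, `kpss_statistic`, `kpss_p`,
#'   `nonstationary`.
#' @seealso [cohort_characteristics()] for the cohort-level aggregation.
#' @export
data_characteristics <- function(data, min_minutes = 30) {
  check_record(data)
  if (!"phase" %in% names(data)) data$phase <- NA_integer_
  data |>
    dplyr::group_by(.data$patient_id, .data$phase, .data$variable) |>
    dplyr::group_modify(function(d, key) {
      grid_n <- max(d$minute) - min(d$minute) + 1
      obs <- d$value[d$status == "observed" & !is.na(d$value)]
      n_obs <- length(obs)
      if (n_obs < min_minutes) {
        return(tibble(
          n_observed = n_obs, sd_percent = NA_real_,
          availability_percent = 100 * n_obs / grid_n,
          kpss_statistic = NA_real_, kpss_p = NA_real_,
          nonstationary = NA
        ))
      }
      k <- kpss_test(obs)
      tibble(
        n_observed = n_obs,
        sd_percent = 100 * stats::sd(obs) / abs(mean(obs)),
        availability_percent = 100 * n_obs / grid_n,
        kpss_statistic = k$statistic, kpss_p = k$p_value,
        nonstationary = k$p_value <= 0.01
      )
    }) |>
    dplyr::ungroup()
}

#' Cohort-level data characteristics
#'
#' Aggregates [data_characteristics()] across patients per channel (and
#' phase): mean SD-percent, mean availability, and the nonstationary fraction
#' — the number of patients whose KPSS p-value is at or below 0.01 divided by
#' the number of patients that have the variable (with reportable metrics).
#'
#' @param characteristics Output of [data_characteristics()].
#' @return Tibble per channel (x phase) with `n_patients`, `mean_sd_percent`,
#'   `mean_availability_percent`, `nonstationary_fraction`.
#' @export
cohort_characteristics <- function(characteristics) {
  characteristics |>
    dplyr::group_by(.data$phase, .data$variable) |>
    dplyr::summarise(
      n_patients = sum(!is.na(.data$nonstationary)),
      mean_sd_percent = mean(.data$sd_percent, na.rm = TRUE),
      mean_availability_percent = mean(.data$availability_percent, na.rm = TRUE),
      nonstationary_fraction = ifelse(
        sum(!is.na(.data$nonstationary)) > 0,
        mean(.data$nonstationary, na.rm = TRUE), NA_real_
      ),
      .groups = "drop"
    )
}
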