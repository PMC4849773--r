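#' Discretize a value into a clinical ordinal state
#'
#' Maps a physiologic value to `LOW`, `NORMAL` or `HIGH` relative to the
#' channel's clinically accepted normal range. The normal range is inclusive
#' at both endpoints (a heart rate of exactly 60 with a 60--80 range is
#' NORMAL); values strictly beyond a bound are LOW/HIGH. One-sided ranges
#' (e.g. ICP normal below 20) produce only the two achievable states.
#'
#' @param x Numeric vector of values (already plausibility-filtered).
#' @param normal_low,normal_high Normal-range bounds; either may be `NA` for
#'   a one-sided range, but not both.
#' @return Character vector of states; `NA` values map to `NA`.
#' @examples
#' bin_value(c(55, 60, 70, 81), normal_low = 60, normal_high = 80)
#' bin_value(25, normal_low = NA, normal_high = 20) # ICP 25 -> HIGH
#' @export
bin_value <- function(x, normal_low, normal_high) {
  if (is.na(normal_low) && is.na(normal_high)) {
    stop("spec has no normal bound on either side; cannot bin", call. = FALSE)
  }
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- "NORMAL"
  if (!is.na(normal_low)) out[ok & x < normal_low] <- "LOW"
  if (!is.na(normal_high)) out[ok & x > normal_high] <- "HIGH"
  out
}

#' Discretize a patient record into ordinal state series
#'
#' Applies [bin_value()] element-wise to every channel of a long record
#' tibble. Channels whose spec has no normal range at all (e.g. brain water
#' content TW%) are binned by per-patient tertiles of their non-missing
#' values, and flagged with `binning = "tertile"` in the output; all other
#' channels carry `binning = "range"`. Missing values propagate to missing
#' states.
#'
#' @param data Long record tibble (`patient_id`, `variable`, `minute`,
#'   `value`, `status`).
#' @param specs Spec tibble from [variable_specs()].
#' @return The input with added columns `state` (character) and `binning`.
#' @export
bin_record <- function(data, specs = variable_specs()) {
  check_record(data)
  unknown <- setdiff(unique(data$variable), specs$variable)
  if (length(unknown) > 0L) {
    stop("no specification for channel(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  sp <- specs[match(data$variable, specs$variable), ]
  tertile <- is.na(sp$normal_low) & is.na(sp$normal_high)
  out <- data
  out$state <- NA_character_
  out$binning <- ifelse(tertile, "tertile", "range")
  rng <- !tertile
  if (any(rng)) {
    out$state[rng] <- dplyr::if_else(
      is.na(data$value[rng]), NA_character_,
      dplyr::case_when(
        !is.na(sp$normal_low[rng]) & data$value[rng] < sp$normal_low[rng] ~ "LOW",
        !is.na(sp$normal_high[rng]) & data$value[rng] > sp$normal_high[rng] ~ "HIGH",
        TRUE ~ "NORMAL"
      )
    )
  }
  if (any(tertile)) {
    # tertile channels: thresholds from this patient('s phase) only
    ph <- if ("phase" %in% names(data)) data$phase[tertile] else 0L
    grp <- interaction(data$patient_id[tertile], data$variable[tertile], ph,
      drop = TRUE
    )
    vals <- split(data$value[tertile], grp)
    states <- lapply(vals, function(v) {
      q <- stats::quantile(v, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE)
      s <- rep(NA_character_, length(v))
      ok <- !is.na(v)
      s[ok] <- "NORMAL"
      s[ok & v < q[1]] <- "LOW"
      s[ok & v > q[2]] <- "HIGH"
      s
    })
    out$state[tertile] <- unsplit(states, grp)
  }
  out
}
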