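#' Aggregate per-patient models into a population summary
#'
#' Counts, for every relationship, how many patients show it as significant
#' and how many patients had the pair of variables measured at all — the
#' denominator is always the number of patients measuring both channels,
#' independent of significance. Reported both per window and collapsed
#' across windows (a relationship is present in a patient if significant in
#' any window; the per-window table is the uncollapsed view). The direction
#' breakdown counts patients with an increasing vs decreasing effect.
#'
#' @param models Result tibble from [infer_cohort()] (a single phase).
#' @param measured Tibble from [measured_channels()] giving patient-channel
#'   presence for the same phase.
#' @param collapse_windows Collapse across windows (default `FALSE`).
#' @return Tibble per relationship: `cause_variable`, `cause_state`,
#'   `effect` (and `r`, `s` unless collapsed), `n_significant`,
#'   `n_measured`, `percent`, `n_increase`, `n_decrease`,
#'   `mean_abs_epsilon`.
#' @export
summarize_population <- function(models, measured, collapse_windows = FALSE) {
  pair_measured <- function(cv, ev) {
    wide <- measured |>
      dplyr::filter(.data$measured) |>
      dplyr::distinct(.data$patient_id, .data$variable)
    both <- dplyr::inner_join(
      wide |> dplyr::filter(.data$variable == cv) |> dplyr::select("patient_id"),
      wide |> dplyr::filter(.data$variable == ev) |> dplyr::select("patient_id"),
      by = "patient_id"
    )
    nrow(both)
  }
  if (nrow(models) == 0L) {
    return(tibble(
      cause_variable = character(), cause_state = character(),
      effect = character(), n_significant = integer(),
      n_measured = integer(), percent = double(),
      n_increase = integer(), n_decrease = integer(),
      mean_abs_epsilon = double()
    ))
  }
  keys <- if (collapse_windows) {
    c("cause_variable", "cause_state", "effect")
  } else {
    c("cause_variable", "cause_state", "effect", "r", "s")
  }
  sig <- models |>
    dplyr::filter(.data$significant) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "patient_id")))) |>
    dplyr::summarise(
      # per patient: dominant direction by largest |epsilon|
      sign = .data$sign[which.max(abs(.data$epsilon))],
      abs_epsilon = max(abs(.data$epsilon)),
      .groups = "drop"
    )
  out <- sig |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_significant = dplyr::n_distinct(.data$patient_id),
      n_increase = sum(.data$sign == "INCREASE"),
      n_decrease = sum(.data$sign == "DECREASE"),
      mean_abs_epsilon = mean(.data$abs_epsilon),
      .groups = "drop"
    )
  out$n_measured <- unname(mapply(pair_measured, out$cause_variable, out$effect))
  out$percent <- 100 * out$n_significant / out$n_measured
  dplyr::relocate(out, "n_measured", "percent", .after = "n_significant")
}

#' Export a population summary as a directed edge list
#'
#' Filters a (window-collapsed) population summary to relationships found in
#' at least `min_percent` of measuring patients and returns a directed edge
#' list with frequency, percent and dominant sign annotations. A
#' relationship significant in both directions appears as two opposing
#' edges. Suitable for igraph/DOT rendering.
#'
#' @param summary Output of [summarize_population()].
#' @param min_percent Minimum percent of measuring patients.
#' @return Tibble `from` (cause, with state), `to` (effect), `cause_state`,
#'   `n_significant`, `n_measured`, `percent`, `dominant_sign`.
#' @export
export_graph <- function(summary, min_percent = 0) {
  summary |>
    dplyr::filter(.data$percent >= min_percent) |>
    dplyr::transmute(
      from = .data$cause_variable,
      to = .data$effect,
      cause_state = .data$cause_state,
      n_significant = .data$n_significant,
      n_measured = .data$n_measured,
      percent = .data$percent,
      dominant_sign = dplyr::case_when(
        .data$n_increase > .data$n_decrease ~ "INCREASE",
        .data$n_decrease > .data$n_increase ~ "DECREASE",
        TRUE ~ "MIXED"
      )
    )
}

#' Score recovery of planted causal structure
#'
#' Compares cohort-level called relationships against the planted edges of a
#' synthetic cohort. Calling operates at the granularity of the population
#' summary's relationships — (cause channel, cause state, effect channel,
#' window): a relationship is called when significant in at least
#' `call_threshold` percent of the patients measuring both channels.
#'
#' * Recall: fraction of planted edges with at least one called relationship
#'   matching their exact (cause variable, cause state, effect).
#' * Precision: fraction of called directed channel pairs that correspond to
#'   a planted edge between those channels. Scoring precision at the channel
#'   pair level reflects that a planted shift of one state necessarily
#'   displaces the effect's conditional mean for the complementary states of
#'   the same cause channel — those detections are attributions to the true
#'   mechanism, not false structure.
#' * Window consistency: for each recovered edge, the called window `[r, s]`
#'   carrying the most evidence (largest significant-patient count, then
#'   mean absolute causal significance) must intersect the planted effect
#'   interval `[lag, lag + duration)` — i.e. `lag` in
#'   `[r - duration + 1, s]`.
#' * Sign consistency: the dominant recovered direction over the edge's
#'   called relationships matches the sign of the planted effect size.
#'
#' @param models Result tibble from [infer_cohort()] on the cohort.
#' @param measured Tibble from [measured_channels()].
#' @param edges Planted-edge tibble (the cohort's ground truth).
#' @param call_threshold Percent of measuring patients required to call a
#'   relationship.
#' @return List: `recall`, `precision`, `window_consistent` (fraction of
#'   recovered edges), `sign_consistent` (fraction), `called` (tibble of
#'   called relationships), `edge_detail` (per planted edge).
#' @export
score_recovery <- function(models, measured, edges, call_threshold = 30) {
  summ <- summarize_population(models, measured, collapse_windows = FALSE)
  called <- summ |> dplyr::filter(.data$percent >= call_threshold)
  if (!"duration_minutes" %in% names(edges)) edges$duration_minutes <- 5L
  # per planted edge: called? best window? dominant sign?
  detail <- edges |>
    dplyr::rowwise() |>
    dplyr::group_map(function(ed, ...) {
      hit <- called |>
        dplyr::filter(
          .data$cause_variable == ed$cause_variable,
          .data$cause_state == ed$cause_state,
          .data$effect == ed$effect_variable
        ) |>
        dplyr::arrange(
          dplyr::desc(.data$n_significant),
          dplyr::desc(.data$mean_abs_epsilon)
        )
      recovered <- nrow(hit) > 0L
      best_r <- NA_integer_
      best_s <- NA_integer_
      dom_sign <- NA_character_
      win_ok <- NA
      sign_ok <- NA
      if (recovered) {
        best_r <- hit$r[1]
        best_s <- hit$s[1]
        win_ok <- ed$lag_minutes >= best_r - ed$duration_minutes + 1 &
          ed$lag_minutes <= best_s
        dom_sign <- ifelse(sum(hit$n_increase) >= sum(hit$n_decrease),
          "INCREASE", "DECREASE"
        )
        sign_ok <- dom_sign == ifelse(ed$effect_size > 0, "INCREASE", "DECREASE")
      }
      tibble(
        cause_variable = ed$cause_variable, cause_state = ed$cause_state,
        effect = ed$effect_variable, lag_minutes = ed$lag_minutes,
        effect_size = ed$effect_size, recovered = recovered,
        best_r = best_r, best_s = best_s, dominant_sign = dom_sign,
        window_consistent = win_ok, sign_consistent = sign_ok
      )
    }) |>
    dplyr::bind_rows()
  true_pairs <- unique(paste(edges$cause_variable, edges$effect_variable))
  called_pairs <- unique(paste(called$cause_variable, called$effect))
  precision <- if (length(called_pairs) == 0L) {
    NA_real_
  } else {
    mean(called_pairs %in% true_pairs)
  }
  rec <- detail$recovered
  list(
    recall = mean(rec),
    precision = precision,
    window_consistent = if (any(rec)) mean(detail$window_consistent[rec]) else NA_real_,
    sign_consistent = if (any(rec)) mean(detail$sign_consistent[rec]) else NA_real_,
    called = called,
    edge_detail = detail
  )
}
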