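#' Default channel dynamics for synthetic cohorts
#'
#' Ten-channel schema modelled on routinely monitored systemic and brain
#' physiologic variables. Each channel follows a Gaussian AR(1) process around
#' its baseline (optionally with a linear drift). Marginal spreads match
#' typical ICU vital signs (e.g. heart rate baseline 75 bpm with a marginal SD
#' of about 12 bpm); autocorrelation is heterogeneous across channels but
#' innovation-dominated (AR coefficients 0.70--0.90), so that statistically
#' independent channel pairs rarely pass the prima facie screen at study-scale
#' series lengths — the regime the inference benchmarks presume. Real
#' monitoring data can be more persistent (up to nonstationary); persistence
#' is explored via the `drift` column and dedicated nonstationarity tests
#' rather than baked into the cohort defaults.
#'
#' @return Tibble with columns `variable`, `baseline`, `ar1`, `noise_sd`,
#'   `drift` (units per minute, default 0).
#' @export
channel_profiles <- function() {
  p <- tibble::tribble(
    ~variable, ~baseline, ~ar1, ~marginal_sd,
    "HR",      75,   0.85, 12,
    "MAP",     90,   0.82, 12,
    "ICP",     12,   0.85,  6,
    "RR",      16,   0.70,  4,
    "TMP",     37.2, 0.90,  0.6,
    "CO2EX",   38,   0.78,  5,
    "SPO2",    97,   0.70,  2,
    "CVP",      6,   0.75,  3,
    "pbtO2",   25,   0.85,  8,
    "rCBF",    40,   0.80, 12
  )
  tibble(
    variable = p$variable, baseline = p$baseline, ar1 = p$ar1,
    noise_sd = p$marginal_sd * sqrt(1 - p$ar1^2), drift = 0
  )
}

#' Missingness mechanism configuration
#'
#' Two mechanisms of data loss seen in clinical monitoring: dropout blocks
#' that depend on the variable itself (a single device malfunctioning), and
#' disconnection events that hit all channels simultaneously (the monitor
#' unplugged for an intervention). Block starts are Poisson; block lengths
#' geometric — the simplest memoryless model of device dropout.
#'
#' @param self_block_rate Expected per-channel dropout blocks per 24 h.
#' @param self_block_mean_minutes Mean self-block length (geometric).
#' @param cross_block_rate Expected all-channel disconnections per 24 h.
#' @param cross_block_mean_minutes Mean cross-block length (geometric).
#' @param channel_availability Optional target fraction of minutes present,
#'   either a single number for all channels or a named vector by variable.
#'   When set for a channel it replaces `self_block_rate`: geometric blocks
#'   are drawn until the channel's missing-minute count reaches the target.
#' @return A `nc_missingness` list.
#' @export
missingness_config <- function(self_block_rate = 0,
                               self_block_mean_minutes = 20,
                               cross_block_rate = 0,
                               cross_block_mean_minutes = 15,
                               channel_availability = NULL) {
  stopifnot(
    self_block_rate >= 0, cross_block_rate >= 0,
    self_block_mean_minutes >= 1, cross_block_mean_minutes >= 1
  )
  if (!is.null(channel_availability)) {
    stopifnot(all(channel_availability > 0), all(channel_availability <= 1))
  }
  structure(
    list(
      self_block_rate = self_block_rate,
      self_block_mean_minutes = self_block_mean_minutes,
      cross_block_rate = cross_block_rate,
      cross_block_mean_minutes = cross_block_mean_minutes,
      channel_availability = channel_availability
    ),
    class = "nc_missingness"
  )
}

#' Synthetic cohort configuration
#'
#' Bundles everything needed to generate a seeded cohort: channel dynamics,
#' planted lagged cause-state -> effect relationships, missingness mechanisms,
#' optional per-patient channel presence, and the master seed. Generation is a
#' pure function of the configuration, so a stored config regenerates an
#' identical cohort.
#'
#' Planted edges are given as a tibble with columns `cause_variable`,
#' `cause_state` (`"LOW"`/`"NORMAL"`/`"HIGH"`), `effect_variable`,
#' `lag_minutes` (>= 1: causes precede effects), `effect_size` (shift in
#' effect units applied to the mean of the effect channel over
#' `[t + lag, t + lag + duration)` whenever the cause channel is in the cause
#' state at minute `t`) and optionally `duration_minutes` (default 5, so an
#' effect lands inside a single 5-minute analysis window).
#'
#' @param n_patients Number of patients (>= 1).
#' @param duration Minutes of monitoring per patient.
#' @param channels Channel dynamics tibble, see [channel_profiles()].
#' @param edges Planted-edge tibble, or `NULL` for no causal structure.
#' @param missingness [missingness_config()], or `NULL` for fully observed.
#' @param channel_presence Optional named vector of per-channel presence
#'   probabilities in (0, 1], emulating devices absent in some patients.
#' @param seed Master integer seed; per-patient seeds are derived from it by
#'   a fixed congruential scheme.
#' @param specs Spec tibble used to bin cause channels into states.
#' @return A `nc_cohort_config` list.
#' @export
cohort_config <- function(n_patients = 1, duration = 5760,
                          channels = channel_profiles(), edges = NULL,
                          missingness = NULL, channel_presence = NULL,
                          seed = 1, specs = variable_specs()) {
  stopifnot(n_patients >= 1, duration >= 1)
  channels <- as_tibble(channels)
  stopifnot(all(c("variable", "baseline", "ar1", "noise_sd") %in% names(channels)))
  if (!"drift" %in% names(channels)) channels$drift <- 0
  stopifnot(all(channels$ar1 >= 0), all(channels$ar1 < 1))
  sp <- specs[match(channels$variable, specs$variable), ]
  if (anyNA(sp$variable)) {
    stop("channels missing from specs: ",
      paste(setdiff(channels$variable, specs$variable), collapse = ", "),
      call. = FALSE
    )
  }
  out_of_bounds <- channels$baseline < sp$plausibility_low |
    channels$baseline > sp$plausibility_high
  if (any(out_of_bounds)) {
    stop("baseline outside plausibility bounds for: ",
      paste(channels$variable[out_of_bounds], collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(edges)) {
    edges <- as_tibble(edges)
    if (!"duration_minutes" %in% names(edges)) edges$duration_minutes <- 5L
    stopifnot(
      all(edges$lag_minutes >= 1),
      all(edges$cause_variable != edges$effect_variable),
      all(is.finite(edges$effect_size)), all(edges$effect_size != 0),
      all(edges$cause_variable %in% channels$variable),
      all(edges$effect_variable %in% channels$variable)
    )
  }
  if (!is.null(missingness)) stopifnot(inherits(missingness, "nc_missingness"))
  if (!is.null(channel_presence)) {
    stopifnot(
      !is.null(names(channel_presence)),
      all(names(channel_presence) %in% channels$variable),
      all(channel_presence > 0), all(channel_presence <= 1)
    )
  }
  structure(
    list(
      n_patients = as.integer(n_patients), duration = as.integer(duration),
      channels = channels, edges = edges, missingness = missingness,
      channel_presence = channel_presence, seed = as.integer(seed),
      specs = specs
    ),
    class = "nc_cohort_config"
  )
}

# Order channels so every cause is generated before its effects; on a cyclic
# edge set falls back to the declared channel order.
topo_channel_order <- function(vars, edges) {
  if (is.null(edges) || nrow(edges) == 0L) {
    return(vars)
  }
  deps <- lapply(vars, function(v) unique(edges$cause_variable[edges$effect_variable == v]))
  names(deps) <- vars
  out <- character(0)
  remaining <- vars
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(
      remaining,
      function(v) all(deps[[v]] %in% out), logical(1)
    )]
    if (length(ready) == 0L) { # cycle: keep declared order
      out <- c(out, remaining)
      break
    }
    out <- c(out, ready)
    remaining <- setdiff(remaining, ready)
  }
  out
}

# Union indicator of [t + lag, t + lag + dur) over trigger minutes t (1-based
# index positions), clipped to 1..n.
shift_indicator <- function(trigger_idx, lag, dur, n) {
  hits <- integer(n)
  for (off in seq_len(dur) - 1L) {
    pos <- trigger_idx + lag + off
    pos <- pos[pos >= 1L & pos <= n]
    hits[pos] <- hits[pos] + 1L
  }
  hits > 0L
}

# Bin one channel's values into states using its spec row (tertiles when the
# spec has no normal range at all).
channel_states <- function(values, spec_row) {
  if (is.na(spec_row$normal_low) && is.na(spec_row$normal_high)) {
    q <- stats::quantile(values, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE)
    s <- rep(NA_character_, length(values))
    ok <- !is.na(values)
    s[ok] <- "NORMAL"
    s[ok & values < q[1]] <- "LOW"
    s[ok & values > q[2]] <- "HIGH"
    s
  } else {
    bin_value(values, spec_row$normal_low, spec_row$normal_high)
  }
}

#' Generate one synthetic patient
#'
#' Simulates complete (fully observed) minute-grid series for every channel in
#' the configuration. Each channel is Gaussian AR(1) around its baseline plus
#' optional drift; planted edges then shift the effect channel's mean by
#' `effect_size` over `[t + lag, t + lag + duration)` whenever the cause
#' channel is in the cause state at minute `t` (overlapping triggers are not
#' additive within an edge). Channels are generated in cause-before-effect
#' order so cause states are taken from the final series. All values are
#' clipped to the channel's plausibility bounds — monitors cannot report
#' impossible values.
#'
#' @param config A [cohort_config()].
#' @param patient_index 1-based index used to derive the patient seed.
#' @return List with `record` (long record tibble, all `status = "observed"`)
#'   and `truth` (list: `edges`, `patient_seed`, `channels_present`).
#' @export
simulate_patient <- function(config, patient_index = 1L) {
  stopifnot(inherits(config, "nc_cohort_config"))
  seed_i <- derive_seed(config$seed, patient_index)
  withr::with_seed(seed_i, {
    ch <- config$channels
    present <- ch$variable
    if (!is.null(config$channel_presence)) {
      keep <- rep(TRUE, nrow(ch))
      names(keep) <- ch$variable
      for (v in names(config$channel_presence)) {
        keep[v] <- stats::runif(1) <= config$channel_presence[[v]]
      }
      present <- ch$variable[keep[ch$variable]]
    }
    n <- config$duration
    t_idx <- seq_len(n)
    sp <- config$specs
    series <- list()
    # base AR(1) dynamics
    for (i in seq_len(nrow(ch))) {
      v <- ch$variable[i]
      if (!(v %in% present)) next
      if (ch$noise_sd[i] > 0 && ch$ar1[i] > 0) {
        init <- stats::rnorm(1, 0, ch$noise_sd[i] / sqrt(1 - ch$ar1[i]^2))
        e <- as.numeric(stats::filter(
          stats::rnorm(n, 0, ch$noise_sd[i]),
          ch$ar1[i],
          method = "recursive", init = init
        ))
      } else if (ch$noise_sd[i] > 0) {
        e <- stats::rnorm(n, 0, ch$noise_sd[i])
      } else {
        e <- numeric(n)
      }
      series[[v]] <- ch$baseline[i] + ch$drift[i] * (t_idx - 1L) + e
    }
    # planted edges, processed so causes are final before binning
    edges <- config$edges
    if (!is.null(edges) && nrow(edges) > 0L) {
      edges <- edges[edges$cause_variable %in% present &
        edges$effect_variable %in% present, , drop = FALSE]
    }
    ord <- topo_channel_order(present, edges)
    for (v in ord) {
      row <- match(v, ch$variable)
      if (!is.null(edges) && nrow(edges) > 0L) {
        into <- which(edges$effect_variable == v)
        for (k in into) {
          cv <- edges$cause_variable[k]
          st <- channel_states(
            pmin(
              pmax(series[[cv]], sp$plausibility_low[match(cv, sp$variable)]),
              sp$plausibility_high[match(cv, sp$variable)]
            ),
            sp[match(cv, sp$variable), ]
          )
          trig <- which(st == edges$cause_state[k])
          if (length(trig) > 0L) {
            u <- shift_indicator(
              trig, edges$lag_minutes[k],
              edges$duration_minutes[k], n
            )
            series[[v]] <- series[[v]] + edges$effect_size[k] * u
          }
        }
      }
      series[[v]] <- pmin(
        pmax(series[[v]], sp$plausibility_low[match(v, sp$variable)]),
        sp$plausibility_high[match(v, sp$variable)]
      )
    }
    series <- series[sort(names(series))]
    record <- tibble(
      patient_id = sprintf("P%03d", patient_index),
      variable = rep(names(series), each = n),
      minute = rep(seq_len(n) - 1L, times = length(series)),
      value = unlist(series, use.names = FALSE),
      status = "observed"
    )
    truth <- list(
      edges = edges, patient_seed = seed_i,
      channels_present = names(series)
    )
    list(record = record, truth = truth)
  })
}

#' Inject ICU-style missingness into a fully observed record
#'
#' Applies the two missingness mechanisms of [missingness_config()]: per
#' channel self-dropout blocks (independent across channels) and cross-channel
#' disconnection blocks that delete every channel over the same minutes.
#' Observed values outside the deleted blocks are untouched; the deleted true
#' values are retained in the returned mask so imputation accuracy can be
#' scored against ground truth.
#'
#' @param data Long record tibble (one or more patients), fully observed.
#' @param missingness A [missingness_config()].
#' @param seed Integer seed.
#' @return List with `record` (masked tibble: value `NA`, status `"missing"`)
#'   and `mask` (tibble `patient_id`, `variable`, `minute`, `true_value`,
#'   `mechanism`).
#' @export
inject_missingness <- function(data, missingness, seed = 1L) {
  check_record(data)
  stopifnot(inherits(missingness, "nc_missingness"))
  mc <- missingness
  patients <- unique(data$patient_id)
  out <- vector("list", length(patients))
  masks <- vector("list", length(patients))
  for (pi in seq_along(patients)) {
    pdat <- data[data$patient_id == patients[pi], ]
    m <- record_matrices(pdat)
    n <- length(m$minutes)
    vars <- colnames(m$values)
    withr::with_seed(derive_seed(seed, pi), {
      mech <- matrix(NA_character_, n, length(vars), dimnames = list(NULL, vars))
      # cross-channel disconnections first
      n_cross <- stats::rpois(1, mc$cross_block_rate * n / 1440)
      if (n_cross > 0L) {
        for (b in seq_len(n_cross)) {
          len <- 1L + stats::rgeom(1, 1 / mc$cross_block_mean_minutes)
          start <- sample.int(n, 1)
          idx <- start:min(n, start + len - 1L)
          mech[idx, ] <- "cross"
        }
      }
      # per-channel self blocks
      for (v in vars) {
        avail <- mc$channel_availability
        if (!is.null(avail)) {
          a <- if (is.null(names(avail))) avail[[1]] else avail[[v]]
        } else {
          a <- NULL
        }
        self_miss <- rep(FALSE, n)
        if (!is.null(a) && !is.na(a) && a < 1) {
          target <- round((1 - a) * n)
          tries <- 0L
          while (sum(self_miss) < target && tries < 50L * n) {
            len <- 1L + stats::rgeom(1, 1 / mc$self_block_mean_minutes)
            start <- sample.int(n, 1)
            self_miss[start:min(n, start + len - 1L)] <- TRUE
            tries <- tries + 1L
          }
        } else if (is.null(a) && mc$self_block_rate > 0) {
          n_self <- stats::rpois(1, mc$self_block_rate * n / 1440)
          for (b in seq_len(n_self)) {
            len <- 1L + stats::rgeom(1, 1 / mc$self_block_mean_minutes)
            start <- sample.int(n, 1)
            self_miss[start:min(n, start + len - 1L)] <- TRUE
          }
        }
        j <- match(v, vars)
        newly <- self_miss & is.na(mech[, j])
        mech[newly, j] <- "self"
      }
      # delete only entries that were actually present
      was_present <- !is.na(m$values)
      kill <- !is.na(mech) & was_present
      mask_tbl <- tibble(
        patient_id = m$patient_id,
        variable = rep(vars, each = n)[as.vector(kill)],
        minute = rep(m$minutes, times = length(vars))[as.vector(kill)],
        true_value = m$values[kill],
        mechanism = mech[kill]
      )
      m$values[kill] <- NA_real_
      m$status[kill] <- "missing"
      out[[pi]] <- matrices_record(m)
      masks[[pi]] <- mask_tbl
    })
  }
  list(record = dplyr::bind_rows(out), mask = dplyr::bind_rows(masks))
}

#' Generate a full synthetic cohort
#'
#' Runs [simulate_patient()] for every patient (seeds derived deterministically
#' from the cohort seed) and, when the configuration includes a missingness
#' model, [inject_missingness()]. Identical configurations always regenerate
#' identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return A `nc_cohort` list: `observations` (long record tibble over all
#'   patients, after any missingness injection), `complete` (the pre-deletion
#'   records), `truth` (list: `edges`, `mask`), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "nc_cohort_config"))
  sims <- lapply(seq_len(config$n_patients), function(i) {
    simulate_patient(config, i)
  })
  complete <- dplyr::bind_rows(lapply(sims, `[[`, "record"))
  if (!is.null(config$missingness)) {
    inj <- inject_missingness(complete, config$missingness,
      seed = derive_seed(config$seed, 999983L)
    )
    observations <- inj$record
    mask <- inj$mask
  } else {
    observations <- complete
    mask <- tibble(
      patient_id = character(), variable = character(),
      minute = integer(), true_value = double(), mechanism = character()
    )
  }
  structure(
    list(
      observations = observations, complete = complete,
      truth = list(edges = config$edges, mask = mask),
      config = config
    ),
    class = "nc_cohort"
  )
}

#' Reference synthetic study designs
#'
#' Frozen cohort configurations used throughout the package's benchmarks and
#' documentation:
#'
#' * `config_null_cohort()`: ten independent channels, no planted edges, fully
#'   observed — the null design for significance-calibration studies.
#' * `config_recovery_cohort()`: twenty patients, ten channels, eight planted
#'   edges (effect sizes about one marginal SD, lags 5--30 minutes, 5-minute
#'   persistence) arranged cause/effect-disjoint, with about 20% mixed-mechanism
#'   missingness — the edge-recovery design.
#' * `config_coupled_cohort()`: six tightly coupled cardiorespiratory channels
#'   (sustained both-direction couplings, so channels carry real mutual
#'   information) with tunable mixed-mechanism missingness — the imputation
#'   benchmark design.
#'
#' @param n_patients,duration,seed Cohort size, minutes per patient, seed.
#' @return A [cohort_config()].
#' @export
config_null_cohort <- function(n_patients = 1, duration = 4800, seed = 1) {
  cohort_config(
    n_patients = n_patients, duration = duration,
    channels = channel_profiles(), edges = NULL, missingness = NULL,
    seed = seed
  )
}

#' @rdname config_null_cohort
#' @export
config_recovery_cohort <- function(n_patients = 20, duration = 4800, seed = 1) {
  edges <- tibble::tribble(
    ~cause_variable, ~cause_state, ~effect_variable, ~lag_minutes, ~effect_size,
    "ICP",   "HIGH", "HR",     8L,  12,
    "ICP",   "HIGH", "pbtO2", 15L,  -8,
    "MAP",   "LOW",  "rCBF",   5L, -12,
    "MAP",   "HIGH", "CVP",   12L,   3,
    "CO2EX", "HIGH", "rCBF",  21L,  10,
    "CO2EX", "LOW",  "SPO2",  18L, -1.8,
    "TMP",   "LOW",  "HR",    25L, -10,
    "MAP",   "LOW",  "pbtO2", 30L,  -8
  )
  edges$duration_minutes <- 5L
  cohort_config(
    n_patients = n_patients, duration = duration,
    channels = channel_profiles(), edges = edges,
    missingness = missingness_config(
      self_block_mean_minutes = 20,
      cross_block_rate = 5.76, cross_block_mean_minutes = 15,
      channel_availability = 0.86
    ),
    seed = seed
  )
}

#' @rdname config_null_cohort
#' @param missing_fraction Overall target missing fraction in `[0, 1)`; split
#'   roughly 60% self-dropout / 40% cross-channel disconnection.
#' @export
config_coupled_cohort <- function(n_patients = 1, duration = 2880,
                                  missing_fraction = 0.2, seed = 1) {
  stopifnot(missing_fraction >= 0, missing_fraction < 1)
  # smooth, strongly autocorrelated dynamics: imputation accuracy is only a
  # meaningful target on channels with predictable structure, as real
  # minute-averaged vitals have
  # the design exercises the two structures the combined imputer addresses:
  # driver channels (MAP, RR) are very smooth — their own spectral structure
  # is the best predictor; driven channels owe most of their variance to
  # large driver-induced shifts with small intrinsic noise — other channels
  # are the best predictor. Driver baselines sit near the normal-range
  # boundary so the driving states hold ~40-50% of minutes and their
  # indicators carry variance.
  p <- tibble::tribble(
    ~variable, ~baseline, ~ar1, ~marginal_sd,
    "MAP",  108,   0.99,  12,
    "RR",    17.5, 0.985,  4,
    "HR",    75,   0.96,  2.5,
    "ICP",   12,   0.96,  1.2,
    "CVP",    6,   0.96,  0.7,
    "CO2EX", 38,   0.96,  1.0,
    "SPO2",  95,   0.96,  0.8,
    "pbtO2", 25,   0.96,  1.5
  )
  ch <- tibble(
    variable = p$variable, baseline = p$baseline, ar1 = p$ar1,
    noise_sd = p$marginal_sd * sqrt(1 - p$ar1^2), drift = 0
  )
  edges <- tibble::tribble(
    ~cause_variable, ~cause_state, ~effect_variable, ~lag_minutes, ~effect_size,
    "MAP", "HIGH", "HR",    3L, -12,
    "MAP", "HIGH", "ICP",   5L,   6,
    "MAP", "HIGH", "CVP",   2L,  -3,
    "MAP", "HIGH", "pbtO2", 6L,   7,
    "RR",  "HIGH", "CO2EX", 4L,  -5,
    "RR",  "HIGH", "SPO2",  3L,  2.5
  )
  edges$duration_minutes <- 10L
  mis <- NULL
  if (missing_fraction > 0) {
    # device-heterogeneous dropout: the driver channels come from
    # near-continuous sources (arterial line, ventilator) and keep a small,
    # level-independent deficit; the probe-based driven channels carry the
    # bulk of the dropout and scale with the requested level; brief
    # all-channel disconnections add the cross mechanism at every level
    d_driven <- pmin(0.95, pmax(0.01, (missing_fraction - 0.0425) * 8 / 6))
    avail <- c(
      MAP = 0.95, RR = 0.95,
      HR = 1 - d_driven, ICP = 1 - d_driven,
      CVP = 1 - d_driven, CO2EX = 1 - d_driven,
      SPO2 = 1 - d_driven, pbtO2 = 1 - d_driven
    )
    mis <- missingness_config(
      self_block_mean_minutes = 12,
      cross_block_rate = 0.03 * 1440 / 8,
      cross_block_mean_minutes = 8,
      channel_availability = pmax(avail, 0.05)
    )
  }
  cohort_config(
    n_patients = n_patients, duration = duration, channels = ch,
    edges = edges, missingness = mis, seed = seed
  )
}

#' Which channels are measured for each patient
#'
#' A channel counts as measured for a patient if the record contains at least
#' one non-missing value for it — the denominator rule used when population
#' summaries report the share of patients exhibiting a relationship.
#'
#' @param data Long record tibble.
#' @return Tibble `patient_id`, `variable`, `measured` (logical).
#' @export
measured_channels <- function(data) {
  check_record(data)
  data |>
    dplyr::group_by(.data$patient_id, .data$variable) |>
    dplyr::summarise(measured = any(!is.na(.data$value)), .groups = "drop")
}
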