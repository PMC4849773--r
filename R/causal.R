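#' Analysis time windows
#'
#' The default timescale grid for causal inference: contiguous,
#' non-overlapping 5-minute windows covering lags 1 to 60 minutes —
#' `[1,5], [6,10], ..., [56,60]`. The lower bound of the first window is 1,
#' never 0: causes must occur strictly before their effects. Overlapping
#' grids are available via `step < width`.
#'
#' @param width Window width in minutes.
#' @param horizon Largest lag considered (minutes).
#' @param step Offset between consecutive windows; defaults to `width`
#'   (non-overlapping).
#' @return Tibble with columns `r`, `s` (window `[t + r, t + s]`).
#' @examples
#' causal_windows() # 12 windows
#' @export
causal_windows <- function(width = 5, horizon = 60, step = width) {
  r <- seq(1, horizon - width + 1, by = step)
  tibble(r = as.integer(r), s = as.integer(r + width - 1))
}

# Windowed means of a standardized effect series. Returns a length-n vector:
# entry t = mean of the non-missing values of z over minutes [t+r, t+s]
# (1-based), NA when fewer than min_support of the window's minutes are
# present or the window runs off the grid.
window_means <- function(z, r, s, min_support = 3) {
  n <- length(z)
  z0 <- ifelse(is.na(z), 0, z)
  cnt <- as.numeric(!is.na(z))
  cz <- c(0, cumsum(z0))
  cc <- c(0, cumsum(cnt))
  t_idx <- seq_len(n)
  hi <- t_idx + s
  lo <- t_idx + r
  valid <- hi <= n
  out <- rep(NA_real_, n)
  sums <- cz[pmin(hi, n) + 1L] - cz[pmin(lo, n + 1L)]
  ns <- cc[pmin(hi, n) + 1L] - cc[pmin(lo, n + 1L)]
  ok <- valid & ns >= min_support
  out[ok] <- sums[ok] / ns[ok]
  out
}

# Build cause-state indicator matrices from a state matrix.
# Returns list(A = holds, V = defined, meta = tibble(variable, state)).
state_indicators <- function(states) {
  vars <- colnames(states)
  cols <- list()
  meta <- list()
  for (v in vars) {
    sv <- states[, v]
    present <- intersect(c("LOW", "NORMAL", "HIGH"), unique(sv[!is.na(sv)]))
    for (st in present) {
      cols[[length(cols) + 1L]] <- list(
        A = as.numeric(!is.na(sv) & sv == st),
        V = as.numeric(!is.na(sv))
      )
      meta[[length(meta) + 1L]] <- tibble(variable = v, state = st)
    }
  }
  if (length(cols) == 0L) {
    return(list(
      A = matrix(0, nrow(states), 0), V = matrix(0, nrow(states), 0),
      meta = tibble(variable = character(), state = character())
    ))
  }
  list(
    A = do.call(cbind, lapply(cols, `[[`, "A")),
    V = do.call(cbind, lapply(cols, `[[`, "V")),
    meta = dplyr::bind_rows(meta)
  )
}

# Causal-significance values for one effect channel and one window.
# ew: windowed effect means (NA where undefined); A, V: indicator/validity
# matrices over candidate cause states (already excluding the effect's own
# channel); meta: candidate descriptors.
epsilon_for_window <- function(ew, A, V, meta, n_min = 10, n_joint = 10,
                               screen_threshold = 0.1) {
  ok_t <- !is.na(ew)
  if (sum(ok_t) == 0L || ncol(A) == 0L) {
    return(NULL)
  }
  ewv <- ew[ok_t]
  Av <- A[ok_t, , drop = FALSE]
  Vv <- V[ok_t, , drop = FALSE]
  n_cause <- colSums(Av)
  n_def <- colSums(Vv)
  mean_c <- as.vector(crossprod(Av, ewv))
  mean_c <- ifelse(n_cause > 0, mean_c / n_cause, NA_real_)
  mean_all <- as.vector(crossprod(Vv, ewv))
  mean_all <- ifelse(n_def > 0, mean_all / n_def, NA_real_)
  screen_diff <- mean_c - mean_all
  keep <- which(n_cause >= n_min & !is.na(screen_diff) &
    abs(screen_diff) > screen_threshold)
  if (length(keep) == 0L) {
    return(NULL)
  }
  Ax <- Av[, keep, drop = FALSE]
  Vx <- Vv[, keep, drop = FALSE]
  Bx <- Vx - Ax
  Aw <- Ax * ewv
  N11 <- crossprod(Ax) # joint occurrences c & x
  S11 <- crossprod(Ax, Aw)
  N01 <- crossprod(Bx, Ax) # not-c & x
  S01 <- crossprod(Bx, Aw)
  valid <- N11 >= n_joint & N01 >= n_joint
  diag(valid) <- FALSE
  contrib <- S11 / N11 - S01 / N01
  contrib[!valid] <- NA_real_
  eps <- rowMeans(contrib, na.rm = TRUE)
  n_cond <- rowSums(valid)
  # marginal fallback where no conditioning term survived
  fall <- which(n_cond == 0L)
  for (i in fall) {
    nc1 <- sum(Ax[, i])
    nc0 <- sum(Bx[, i])
    if (nc1 == 0 || nc0 == 0) {
      eps[i] <- NA_real_
    } else {
      eps[i] <- sum(ewv[Ax[, i] == 1]) / nc1 - sum(ewv[Bx[, i] == 1]) / nc0
    }
  }
  res <- meta[keep, , drop = FALSE]
  res$epsilon <- eps
  res$n_cause <- n_cause[keep]
  res$n_conditioning <- n_cond
  res$screen_diff <- screen_diff[keep]
  res[!is.na(res$epsilon), , drop = FALSE]
}

#' Score causal-significance values against a per-patient empirical null
#'
#' Converts a patient-phase population of causal-significance values into
#' z-scores and two-sided p-values against an empirical normal null whose
#' location and scale are robustly estimated (median, and MAD scaled to the
#' normal) from the population itself. A relationship is significant when
#' `p < alpha`; no multiplicity correction is applied — models are inferred
#' per patient and each forms its own small hypothesis family. The effect
#' direction (`INCREASE`/`DECREASE`) is reported for significant results
#' only.
#'
#' Used directly, this scores an existing result table; [infer_patient()]
#' calls it internally and switches to a per-hypothesis circular-shift
#' permutation test when the population is too small (or too degenerate)
#' for a stable empirical null.
#'
#' @param results Tibble with at least an `epsilon` column.
#' @param alpha Significance cutoff (default 0.05).
#' @return `results` with added `z`, `p`, `significant`, `sign`.
#' @export
score_significance <- function(results, alpha = 0.05) {
  if (nrow(results) == 0L) {
    results$z <- numeric(0)
    results$p <- numeric(0)
    results$significant <- logical(0)
    results$sign <- character(0)
    return(results)
  }
  med <- stats::median(results$epsilon)
  scale <- stats::mad(results$epsilon) # already scaled by 1.4826
  if (scale == 0) {
    stop("degenerate epsilon population (MAD = 0); use the permutation path",
      call. = FALSE
    )
  }
  results$z <- (results$epsilon - med) / scale
  results$p <- 2 * stats::pnorm(-abs(results$z))
  results$significant <- results$p < alpha
  results$sign <- dplyr::if_else(
    results$significant,
    dplyr::if_else(results$epsilon > 0, "INCREASE", "DECREASE"),
    NA_character_
  )
  results
}

#' Infer a per-patient causal model
#'
#' The full per-patient (and per-phase) sweep of temporal causal inference:
#' every (cause channel, cause state) -> (effect channel) hypothesis is
#' evaluated at every analysis window. Effects are continuous, standardized
#' to zero mean and unit variance over the patient-phase; causes are the
#' discretized clinical states. For each effect and window, candidate causes
#' are screened to the prima facie set (at least `n_min` occurrences with a
#' defined effect window, and a shift of the windowed effect mean beyond
#' `screen_threshold` SD); the causal significance of each retained cause is
#' the average contrast `E(e_w | c & x) - E(e_w | not-c & x)` over the other
#' prima facie causes `x` (conditioning states evaluated at the same minute
#' as the candidate), skipping conditioning pairs with fewer than `n_joint`
#' joint occurrences on either side, and falling back to the marginal
#' contrast when no conditioning term survives. Significance comes from the
#' patient's empirical null ([score_significance()]); when fewer than
#' `min_null_results` values are available (or the null scale degenerates),
#' a per-hypothesis circular-shift permutation test is used instead.
#'
#' Microdialysis channels are excluded by default: sampled about hourly and
#' never imputed, they cannot meet window support at minute resolution.
#'
#' @param data Long record tibble for one patient (one phase), carrying a
#'   `state` column from [bin_record()]. Imputed values participate exactly
#'   like observed ones; set `observed_only = TRUE` for a sensitivity
#'   analysis restricted to observed entries.
#' @param specs Spec tibble (identifies microdialysis channels).
#' @param windows Window grid from [causal_windows()].
#' @param n_min Minimum cause occurrences for a prima facie cause.
#' @param screen_threshold Prima facie screen on the shift of the windowed
#'   effect mean (in effect SDs).
#' @param n_joint Minimum joint occurrences per conditioning pair side.
#' @param min_window_support Minimum present minutes inside a window for its
#'   mean to be defined.
#' @param min_channel_minutes Channels with fewer non-missing minutes are
#'   excluded from the sweep.
#' @param alpha Significance cutoff.
#' @param min_null_results Smallest epsilon population scored with the
#'   empirical null; below it the permutation path is taken.
#' @param n_perm Circular shifts for the permutation fallback.
#' @param observed_only Ignore imputed entries.
#' @param include_microdialysis Allow hourly microdialysis channels in.
#' @return Tibble with one row per evaluated hypothesis: `patient_id`,
#'   `phase`, `cause_variable`, `cause_state`, `effect`, `r`, `s`,
#'   `epsilon`, `n_cause`, `n_conditioning`, `z`, `p`, `significant`,
#'   `sign`, `null_method`.
#' @export
infer_patient <- function(data, specs = variable_specs(),
                          windows = causal_windows(), n_min = 10,
                          screen_threshold = 0.1, n_joint = 10,
                          min_window_support = 3,
                          min_channel_minutes = 120, alpha = 0.05,
                          min_null_results = 20, n_perm = 200,
                          observed_only = FALSE,
                          include_microdialysis = FALSE) {
  check_record(data)
  if (!"state" %in% names(data)) {
    stop("`data` must carry a `state` column; run bin_record() first",
      call. = FALSE
    )
  }
  stopifnot(length(unique(data$patient_id)) == 1L)
  phase <- if ("phase" %in% names(data)) {
    stopifnot(length(unique(data$phase)) == 1L)
    data$phase[[1L]]
  } else {
    NA_integer_
  }
  empty <- tibble(
    patient_id = character(), phase = integer(),
    cause_variable = character(), cause_state = character(),
    effect = character(), r = integer(), s = integer(),
    epsilon = double(), n_cause = double(), n_conditioning = double(),
    z = double(), p = double(), significant = logical(),
    sign = character(), null_method = character()
  )
  work <- data
  if (!include_microdialysis) {
    md <- specs$variable[specs$microdialysis %in% TRUE]
    work <- work[!(work$variable %in% md), , drop = FALSE]
  }
  if (observed_only) {
    drop <- !(work$status %in% c("observed", "derived"))
    work$value[drop] <- NA_real_
    work$state[drop] <- NA_character_
  }
  if (nrow(work) == 0L) {
    return(empty)
  }
  m <- record_matrices(work)
  n <- nrow(m$values)
  if (n < 120L) {
    warning("phase shorter than 120 minutes; returning empty model",
      call. = FALSE
    )
    return(empty)
  }
  # state matrix aligned with the value grid
  svals <- matrix(NA_character_, n, ncol(m$values),
    dimnames = dimnames(m$values)
  )
  i <- match(work$minute, m$minutes)
  j <- match(work$variable, colnames(m$values))
  svals[cbind(i, j)] <- work$state
  keep_ch <- colSums(!is.na(m$values)) >= min_channel_minutes
  vals <- m$values[, keep_ch, drop = FALSE]
  svals <- svals[, keep_ch, drop = FALSE]
  vars <- colnames(vals)
  if (length(vars) < 2L) {
    return(empty)
  }
  # standardized effects
  zvals <- apply(vals, 2, function(x) {
    mu <- mean(x, na.rm = TRUE)
    sg <- stats::sd(x, na.rm = TRUE)
    if (is.na(sg) || sg == 0) {
      return(rep(NA_real_, length(x)))
    }
    (x - mu) / sg
  })
  ind <- state_indicators(svals)
  res <- list()
  for (e in vars) {
    z <- zvals[, e]
    if (all(is.na(z))) next # constant channel: cannot be an effect
    cand <- which(ind$meta$variable != e)
    if (length(cand) == 0L) next
    A <- ind$A[, cand, drop = FALSE]
    V <- ind$V[, cand, drop = FALSE]
    meta <- ind$meta[cand, , drop = FALSE]
    for (wi in seq_len(nrow(windows))) {
      ew <- window_means(z, windows$r[wi], windows$s[wi],
        min_support = min_window_support
      )
      r <- epsilon_for_window(ew, A, V, meta,
        n_min = n_min,
        n_joint = n_joint, screen_threshold = screen_threshold
      )
      if (is.null(r) || nrow(r) == 0L) next
      r$effect <- e
      r$r <- windows$r[wi]
      r$s <- windows$s[wi]
      r$.window_index <- wi
      res[[length(res) + 1L]] <- r
    }
  }
  results <- dplyr::bind_rows(res)
  if (nrow(results) == 0L) {
    return(empty)
  }
  names(results)[names(results) == "variable"] <- "cause_variable"
  names(results)[names(results) == "state"] <- "cause_state"
  use_empirical <- nrow(results) >= min_null_results &&
    stats::mad(results$epsilon) > 0
  if (use_empirical) {
    results <- score_significance(results, alpha = alpha)
    results$null_method <- "empirical"
  } else {
    results <- permutation_score(results, zvals, ind, windows,
      n_min = n_min, n_joint = n_joint,
      screen_threshold = screen_threshold,
      min_window_support = min_window_support,
      alpha = alpha, n_perm = n_perm
    )
    results$null_method <- "permutation"
  }
  results$patient_id <- m$patient_id
  results$phase <- phase
  dplyr::select(
    results, "patient_id", "phase", "cause_variable", "cause_state",
    "effect", "r", "s", "epsilon", "n_cause", "n_conditioning",
    "z", "p", "significant", "sign", "null_method"
  )
}

# Epsilon for a single candidate (indicator a, validity v) against a fixed
# conditioning pool (columns of Ax/Vx, the prima facie set minus the
# candidate), restricted to minutes where ew is defined.
epsilon_one <- function(ew, a, v, Ax, Vx, n_joint) {
  ok_t <- !is.na(ew)
  ewv <- ew[ok_t]
  a <- a[ok_t]
  b <- v[ok_t] - a
  eps_terms <- c()
  if (!is.null(Ax) && ncol(Ax) > 0L) {
    Ax <- Ax[ok_t, , drop = FALSE]
    for (x in seq_len(ncol(Ax))) {
      n11 <- sum(a * Ax[, x])
      n01 <- sum(b * Ax[, x])
      if (n11 < n_joint || n01 < n_joint) next
      eps_terms <- c(
        eps_terms,
        sum(a * Ax[, x] * ewv) / n11 - sum(b * Ax[, x] * ewv) / n01
      )
    }
  }
  if (length(eps_terms) > 0L) {
    return(mean(eps_terms))
  }
  n1 <- sum(a)
  n0 <- sum(b)
  if (n1 == 0 || n0 == 0) {
    return(NA_real_)
  }
  sum(a * ewv) / n1 - sum(b * ewv) / n0
}

# Permutation fallback: for each retained hypothesis, recompute epsilon under
# n_perm circular time-shifts of the candidate cause's state series, holding
# the effect and the originally screened conditioning pool fixed, and take
# the two-sided rank p-value. Deterministic: shifts are evenly spaced over
# the grid length.
permutation_score <- function(results, zvals, ind, windows, n_min, n_joint,
                              screen_threshold, min_window_support,
                              alpha, n_perm) {
  n <- nrow(zvals)
  shifts <- unique(pmax(1L, floor(seq(1, n - 1, length.out = n_perm))))
  results$z <- NA_real_
  results$p <- NA_real_
  key <- paste(ind$meta$variable, ind$meta$state)
  res_key <- paste(results$cause_variable, results$cause_state)
  for (i in seq_len(nrow(results))) {
    e <- results$effect[i]
    ew <- window_means(zvals[, e], results$r[i], results$s[i],
      min_support = min_window_support
    )
    # conditioning pool: the other prima facie causes retained for this
    # effect/window in the observed data
    same_ew <- results$effect == e & results$r == results$r[i] &
      results$s == results$s[i]
    pool <- setdiff(match(res_key[same_ew], key), match(res_key[i], key))
    Ax <- ind$A[, pool, drop = FALSE]
    Vx <- ind$V[, pool, drop = FALSE]
    ci <- match(res_key[i], key)
    a <- ind$A[, ci]
    v <- ind$V[, ci]
    eps_null <- vapply(shifts, function(sh) {
      ord <- c((sh + 1L):n, 1L:sh)
      epsilon_one(ew, a[ord], v[ord], Ax, Vx, n_joint)
    }, numeric(1))
    eps_null <- eps_null[!is.na(eps_null)]
    if (length(eps_null) == 0L) next
    results$p[i] <- (1 + sum(abs(eps_null) >= abs(results$epsilon[i]))) /
      (1 + length(eps_null))
  }
  results$significant <- !is.na(results$p) & results$p < alpha
  results$sign <- dplyr::if_else(
    results$significant,
    dplyr::if_else(results$epsilon > 0, "INCREASE", "DECREASE"),
    NA_character_
  )
  results
}

#' Infer causal models for a whole cohort
#'
#' Maps [infer_patient()] over every patient (and phase, when the record is
#' phase-labelled) of a cohort record and binds the per-patient models into
#' one result table — inference is always done for each patient separately.
#'
#' @inheritParams infer_patient
#' @param data Long record tibble over one or more patients.
#' @param ... Passed to [infer_patient()].
#' @return Bound tibble of per-patient models.
#' @export
infer_cohort <- function(data, specs = variable_specs(), ...) {
  check_record(data)
  seg <- if ("phase" %in% names(data)) {
    interaction(data$patient_id, data$phase, drop = TRUE)
  } else {
    data$patient_id
  }
  dplyr::bind_rows(lapply(split(data, seg), function(d) {
    infer_patient(d, specs = specs, ...)
  }))
}
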