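# Independent brute-force implementation of windowed causal significance,
# written as explicit loops over minute tables. Deliberately shares no code
# with the package internals; used as the oracle for equivalence tests.

brute_epsilon_patient <- function(values, states, r, s,
                                  n_min = 10, n_joint = 10,
                                  screen_threshold = 0.1, min_support = 3) {
  n <- nrow(values)
  vars <- colnames(values)
  # candidate list: (variable, state) for every state present
  cand <- list()
  for (v in vars) {
    for (st in c("LOW", "NORMAL", "HIGH")) {
      if (any(states[, v] == st, na.rm = TRUE)) {
        cand[[length(cand) + 1L]] <- c(v, st)
      }
    }
  }
  out <- list()
  for (e in vars) {
    mu <- mean(values[, e], na.rm = TRUE)
    sg <- stats::sd(values[, e], na.rm = TRUE)
    if (is.na(sg) || sg == 0) next
    z <- (values[, e] - mu) / sg
    # windowed means by explicit loop
    ew <- rep(NA_real_, n)
    for (t in seq_len(n)) {
      if (t + s > n) next
      seg <- z[(t + r):(t + s)]
      if (sum(!is.na(seg)) >= min_support) ew[t] <- mean(seg, na.rm = TRUE)
    }
    # prima facie screen
    keep <- list()
    for (ci in seq_along(cand)) {
      v <- cand[[ci]][1]
      st <- cand[[ci]][2]
      if (v == e) next
      n_c <- 0L
      sum_c <- 0
      n_all <- 0L
      sum_all <- 0
      for (t in seq_len(n)) {
        if (is.na(ew[t]) || is.na(states[t, v])) next
        n_all <- n_all + 1L
        sum_all <- sum_all + ew[t]
        if (states[t, v] == st) {
          n_c <- n_c + 1L
          sum_c <- sum_c + ew[t]
        }
      }
      if (n_c < n_min || n_all == 0L) next
      diff <- sum_c / n_c - sum_all / n_all
      if (is.na(diff) || abs(diff) <= screen_threshold) next
      keep[[length(keep) + 1L]] <- list(v = v, st = st)
    }
    if (length(keep) == 0L) next
    for (i in seq_along(keep)) {
      cv <- keep[[i]]$v
      cs <- keep[[i]]$st
      terms <- c()
      for (j in seq_along(keep)) {
        if (j == i) next
        xv <- keep[[j]]$v
        xs <- keep[[j]]$st
        n11 <- 0L
        s11 <- 0
        n01 <- 0L
        s01 <- 0
        for (t in seq_len(n)) {
          if (is.na(ew[t]) || is.na(states[t, cv]) || is.na(states[t, xv])) next
          if (states[t, xv] != xs) next
          if (states[t, cv] == cs) {
            n11 <- n11 + 1L
            s11 <- s11 + ew[t]
          } else {
            n01 <- n01 + 1L
            s01 <- s01 + ew[t]
          }
        }
        if (n11 < n_joint || n01 < n_joint) next
        terms <- c(terms, s11 / n11 - s01 / n01)
      }
      if (length(terms) > 0L) {
        eps <- mean(terms)
      } else {
        n1 <- 0L
        su1 <- 0
        n0 <- 0L
        su0 <- 0
        for (t in seq_len(n)) {
          if (is.na(ew[t]) || is.na(states[t, cv])) next
          if (states[t, cv] == cs) {
            n1 <- n1 + 1L
            su1 <- su1 + ew[t]
          } else {
            n0 <- n0 + 1L
            su0 <- su0 + ew[t]
          }
        }
        if (n1 == 0L || n0 == 0L) next
        eps <- su1 / n1 - su0 / n0
      }
      out[[length(out) + 1L]] <- data.frame(
        cause_variable = cv, cause_state = cs, effect = e,
        r = r, s = s, epsilon = eps
      )
    }
  }
  do.call(rbind, c(out, list(data.frame(
    cause_variable = character(), cause_state = character(),
    effect = character(), r = integer(), s = integer(), epsilon = double()
  ))))
}

# Random small inference instance: a binned record tibble plus the matrices
# the oracle consumes.
random_instance <- function(seed, n_channels = 4, n_minutes = 400) {
  withr::with_seed(seed, {
    vars <- sample(c("HR", "MAP", "ICP", "CVP"), n_channels)
    specs <- variable_specs()
    rows <- list()
    for (v in vars) {
      sp <- specs[specs$variable == v, ]
      center <- mean(c(
        ifelse(is.na(sp$normal_low), sp$plausibility_low, sp$normal_low),
        ifelse(is.na(sp$normal_high), sp$plausibility_high, sp$normal_high)
      ))
      spread <- stats::runif(1, 5, 25)
      x <- center + as.numeric(stats::filter(
        stats::rnorm(n_minutes, 0, spread * 0.4), stats::runif(1, 0.3, 0.9),
        method = "recursive"
      ))
      x <- pmin(pmax(x, sp$plausibility_low), sp$plausibility_high)
      x[stats::runif(n_minutes) < stats::runif(1, 0, 0.2)] <- NA
      rows[[v]] <- x
    }
    rec <- dplyr::bind_rows(lapply(vars, function(v) {
      tibble::tibble(
        patient_id = "PX", variable = v, minute = 0:(n_minutes - 1),
        value = rows[[v]],
        status = ifelse(is.na(rows[[v]]), "missing", "observed")
      )
    }))
    bin_record(rec, specs)
  })
}

# Matrices aligned with the grid of a (single-patient) binned record.
instance_matrices <- function(binned) {
  vars <- sort(unique(binned$variable))
  minutes <- seq(min(binned$minute), max(binned$minute))
  values <- matrix(NA_real_, length(minutes), length(vars),
    dimnames = list(NULL, vars)
  )
  states <- matrix(NA_character_, length(minutes), length(vars),
    dimnames = list(NULL, vars)
  )
  i <- match(binned$minute, minutes)
  j <- match(binned$variable, vars)
  values[cbind(i, j)] <- binned$value
  states[cbind(i, j)] <- binned$state
  list(values = values, states = states)
}
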