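test_that("gap tables are exact maximal-run decompositions", {
  rec <- tibble::tibble(
    patient_id = "A", variable = "HR", minute = 0:5,
    value = c(NA, NA, 1, 2, 3, NA),
    status = c("missing", "missing", rep("observed", 3), "missing")
  )
  g <- find_gaps(rec)
  expect_equal(g$start, c(0L, 5L))
  expect_equal(g$length, c(2L, 1L))
  # fully observed channel: empty table
  full <- tibble::tibble(
    patient_id = "A", variable = "HR", minute = 0:9, value = 1,
    status = "observed"
  )
  expect_equal(nrow(find_gaps(full)), 0L)
  # fully missing channel: one run covering the grid
  none <- tibble::tibble(
    patient_id = "A", variable = "HR", minute = 0:9, value = NA_real_,
    status = "missing"
  )
  g2 <- find_gaps(none)
  expect_equal(g2$start, 0L)
  expect_equal(g2$length, 10L)
})

test_that("Fourier reconstruction recovers constants and sinusoids", {
  x <- rep(5, 100)
  x[c(10, 50, 90)] <- NA
  filled <- impute_fourier(x)
  expect_equal(filled[c(10, 50, 90)], rep(5, 3), tolerance = 1e-6)
  # pure sinusoid with 10% missing: near-exact spectral recovery
  withr::with_seed(31, {
    t <- 0:1439
    y <- sin(2 * pi * t / 60)
    miss <- sample(1440, 144)
  })
  y_obs <- y
  y_obs[miss] <- NA
  rec <- impute_fourier(y_obs)
  rmse <- sqrt(mean((rec[miss] - y[miss])^2))
  expect_lt(rmse, 0.05)
  # fewer than two observed values: no estimates
  x2 <- c(1, rep(NA_real_, 9))
  expect_identical(impute_fourier(x2), x2)
})

test_that("Fourier estimates of single holes in smooth series stay in range", {
  for (i in 1:20) {
    withr::with_seed(400 + i, {
      x <- as.numeric(stats::filter(rnorm(500), 0.9, "recursive")) + 50
      hole <- sample(50:450, 1)
    })
    x_obs <- x
    x_obs[hole] <- NA
    est <- impute_fourier(x_obs)[hole]
    expect_gte(est, min(x_obs, na.rm = TRUE))
    expect_lte(est, max(x_obs, na.rm = TRUE))
  }
})

test_that("lagged correlations identify exact lag structure", {
  withr::with_seed(5, {
    x <- as.numeric(stats::filter(rnorm(500), 0.8, "recursive")) + 90
  })
  y <- c(rep(mean(x), 7), x[1:(500 - 7)]) # y(t) = x(t-7)
  y[1:7] <- NA
  rec <- dplyr::bind_rows(
    tibble::tibble(
      patient_id = "A", variable = "MAP", minute = 0:499, value = x,
      status = "observed"
    ),
    tibble::tibble(
      patient_id = "A", variable = "HR", minute = 0:499, value = y,
      status = ifelse(is.na(y), "missing", "observed")
    )
  )
  lc <- lagged_correlations(rec)
  top <- lc[lc$source == "MAP" & lc$target == "HR" & lc$rank == 1, ]
  expect_equal(top$lag, 7L)
  expect_equal(top$correlation, 1.0, tolerance = 1e-10)
  # cardinality never exceeds p = 3 per ordered pair
  expect_true(all(dplyr::count(lc, source, target)$n <= 3))
})

test_that("independent white-noise pairs yield no strong lag", {
  weak <- sapply(1:20, function(i) {
    withr::with_seed(700 + i, {
      rec <- dplyr::bind_rows(
        tibble::tibble(
          patient_id = "A", variable = "HR", minute = 0:1999,
          value = rnorm(2000, 75, 5), status = "observed"
        ),
        tibble::tibble(
          patient_id = "A", variable = "MAP", minute = 0:1999,
          value = rnorm(2000, 90, 5), status = "observed"
        )
      )
    })
    lc <- lagged_correlations(rec)
    pair <- lc[lc$source == "HR" & lc$target == "MAP", ]
    nrow(pair) == 0L || max(abs(pair$correlation)) < 0.1
  })
  expect_gte(mean(weak), 0.95)
})

test_that("lagged k-NN honours exact duplicates and constants", {
  # an exact duplicate of the query's feature vector dominates
  n <- 200
  withr::with_seed(12, {
    x <- rnorm(n, 90, 8)
  })
  x[101:200] <- x[1:100] # duplicate block
  v <- c(1:100, 1:100) * 1.0
  v[50] <- NA # missing where a feature-duplicate minute (150) is observed
  rec <- dplyr::bind_rows(
    tibble::tibble(
      patient_id = "A", variable = "MAP", minute = 0:(n - 1), value = x,
      status = "observed"
    ),
    tibble::tibble(
      patient_id = "A", variable = "HR", minute = 0:(n - 1), value = v,
      status = ifelse(is.na(v), "missing", "observed")
    )
  )
  m <- neurocausal:::record_matrices(rec)
  lagset <- tibble::tibble(
    patient_id = "A", source = "MAP", target = "HR",
    lag = 0L, correlation = 0.9, rank = 1L
  )
  est <- neurocausal:::lknn_estimate(m, lagset, "HR", at = 50, k = 5)
  expect_equal(est, v[150]) # the zero-distance duplicate's value
  # constant target: every estimate equals the constant
  rec2 <- rec
  rec2$value[rec2$variable == "HR"] <- 7
  rec2$value[rec2$variable == "HR"][c(20, 80)] <- NA
  m2 <- neurocausal:::record_matrices(rec2)
  est2 <- neurocausal:::lknn_estimate(m2, lagset, "HR", at = c(20, 80), k = 5)
  expect_equal(est2, c(7, 7))
})

test_that("the 30-minute gap cap is absolute and observed values survive", {
  coh <- simulate_cohort(config_coupled_cohort(
    n_patients = 1, duration = 1440, missing_fraction = 0, seed = 44
  ))
  rec <- coh$observations
  # carve one 45-minute gap and one 10-minute gap into HR
  hr <- rec$variable == "HR"
  gap45 <- rec$minute >= 100 & rec$minute < 145
  gap10 <- rec$minute >= 400 & rec$minute < 410
  rec$value[hr & (gap45 | gap10)] <- NA
  rec$status[hr & (gap45 | gap10)] <- "missing"
  before <- rec
  out <- impute_flknn(rec)
  expect_true(all(is.na(out$value[hr & gap45]))) # 45-min gap untouched
  expect_true(all(out$status[hr & gap45] == "missing"))
  expect_true(all(!is.na(out$value[hr & gap10]))) # 10-min gap filled
  expect_true(all(out$status[hr & gap10] %in%
    c("imputed_f", "imputed_lknn", "imputed_combined")))
  obs <- before$status == "observed"
  expect_identical(out$value[obs], before$value[obs])
})

test_that("hourly-sampled channels are never imputed", {
  # microdialysis-style channel: one value per hour, 59-minute gaps
  minutes <- 0:719
  lact <- ifelse(minutes %% 60 == 0, 3.0, NA)
  rec <- dplyr::bind_rows(
    tibble::tibble(
      patient_id = "A", variable = "lactate", minute = minutes,
      value = lact, status = ifelse(is.na(lact), "missing", "observed")
    ),
    simulate_cohort(config_coupled_cohort(
      n_patients = 1, duration = 720, missing_fraction = 0, seed = 2
    ))$observations
  )
  out <- impute_flknn(rec)
  lac_out <- out[out$variable == "lactate", ]
  expect_equal(sum(!is.na(lac_out$value)), sum(!is.na(lact)))
  expect_true(all(lac_out$status %in% c("observed", "missing")))
})

test_that("combination is the mean of both components where both exist", {
  coh <- simulate_cohort(config_coupled_cohort(
    n_patients = 1, duration = 1440, missing_fraction = 0.15, seed = 19
  ))
  comp <- neurocausal:::impute_components(coh$observations)
  both <- comp[!is.na(comp$est_f) & !is.na(comp$est_lknn), ]
  expect_gt(nrow(both), 0)
  out <- impute_flknn(coh$observations)
  joined <- dplyr::inner_join(
    both, out,
    by = c("patient_id", "variable", "minute")
  )
  expect_equal(joined$value, (joined$est_f + joined$est_lknn) / 2)
  expect_true(all(joined$status == "imputed_combined"))
})

test_that("imputation error degrades monotonely with missingness", {
  b <- impute_benchmark(
    levels = c(0.05, 0.1, 0.2, 0.35, 0.5),
    n_replicates = 3, duration = 1440, seed = 17
  )
  mae <- b |>
    dplyr::filter(method == "flknn") |>
    dplyr::group_by(level) |>
    dplyr::summarise(mae = mean(mae)) |>
    dplyr::arrange(level)
  # allow a single inversion between adjacent levels (sampling tolerance)
  expect_lte(sum(diff(mae$mae) < 0), 1)
})
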