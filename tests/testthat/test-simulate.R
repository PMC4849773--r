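test_that("generation is a pure function of config and seed", {
  cfg <- config_null_cohort(n_patients = 2, duration = 600, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(config_null_cohort(n_patients = 2, duration = 600, seed = 5))
  expect_identical(a$observations, b$observations)
  # distinct patients get distinct series under one config
  p1 <- a$observations[a$observations$patient_id == "P001", ]
  p2 <- a$observations[a$observations$patient_id == "P002", ]
  expect_false(identical(p1$value, p2$value))
})

test_that("degenerate dynamics give constant channels at baseline", {
  ch <- tibble::tibble(
    variable = c("HR", "MAP"), baseline = c(75, 90), ar1 = 0, noise_sd = 0,
    drift = 0
  )
  cfg <- cohort_config(n_patients = 1, duration = 100, channels = ch, seed = 1)
  rec <- simulate_patient(cfg)$record
  expect_true(all(rec$value[rec$variable == "HR"] == 75))
  expect_true(all(rec$value[rec$variable == "MAP"] == 90))
})

test_that("all generated values respect plausibility bounds", {
  cfg <- config_recovery_cohort(n_patients = 2, duration = 1500, seed = 3)
  coh <- simulate_cohort(cfg)
  sp <- variable_specs()
  joined <- dplyr::left_join(coh$complete, sp, by = "variable")
  expect_true(all(joined$value >= joined$plausibility_low))
  expect_true(all(joined$value <= joined$plausibility_high))
})

test_that("a planted edge leaves its lag signature in the cross-correlogram", {
  # ICP HIGH -> HR at lag 10: the indicator/effect cross-correlation must
  # peak within 2 minutes of the planted lag (start of the 5-minute effect)
  ch <- channel_profiles()[channel_profiles()$variable %in% c("HR", "ICP"), ]
  edges <- tibble::tibble(
    cause_variable = "ICP", cause_state = "HIGH", effect_variable = "HR",
    lag_minutes = 10L, effect_size = 15, duration_minutes = 5L
  )
  cfg <- cohort_config(
    n_patients = 1, duration = 4800, channels = ch,
    edges = edges, seed = 21
  )
  rec <- simulate_patient(cfg)$record
  m <- neurocausal:::record_matrices(rec)
  ind <- as.numeric(m$values[, "ICP"] > 20)
  hr <- m$values[, "HR"]
  cors <- sapply(0:30, function(l) {
    n <- length(hr)
    cor(ind[1:(n - l)], hr[(1 + l):n])
  })
  peak <- which.max(cors) - 1L
  expect_true(abs(peak - 10) <= 2 ||
    (peak >= 10 && peak <= 10 + 4)) # anywhere inside the effect interval
  expect_true(abs(peak - 10) <= 4)
})

test_that("zero-rate missingness is the identity", {
  cfg <- config_null_cohort(n_patients = 1, duration = 300, seed = 2)
  coh <- simulate_cohort(cfg)
  inj <- inject_missingness(coh$observations, missingness_config(), seed = 1)
  expect_identical(inj$record$value, coh$observations$value)
  expect_equal(nrow(inj$mask), 0L)
})

test_that("availability targets are hit within tolerance", {
  ch <- channel_profiles()[1, ]
  cfg <- cohort_config(n_patients = 1, duration = 10000, channels = ch, seed = 8)
  rec <- simulate_patient(cfg)$record
  fracs <- sapply(1:20, function(i) {
    inj <- inject_missingness(
      rec, missingness_config(channel_availability = 0.8),
      seed = 600 + i
    )
    mean(!is.na(inj$record$value))
  })
  expect_true(all(abs(fracs - 0.8) < 0.02))
})

test_that("cross-channel blocks delete every channel over the same minutes", {
  cfg <- config_null_cohort(n_patients = 1, duration = 2000, seed = 4)
  coh <- simulate_cohort(cfg)
  inj <- inject_missingness(
    coh$observations,
    missingness_config(cross_block_rate = 3, cross_block_mean_minutes = 40),
    seed = 9
  )
  cross <- inj$mask[inj$mask$mechanism == "cross", ]
  expect_gt(nrow(cross), 0)
  per_minute <- dplyr::count(cross, .data$minute)
  n_channels <- length(unique(coh$observations$variable))
  expect_true(all(per_minute$n == n_channels))
})

test_that("missingness accounting: present plus masked equals the grid", {
  cfg <- config_recovery_cohort(n_patients = 1, duration = 1000, seed = 6)
  coh <- simulate_cohort(cfg)
  acct <- coh$observations |>
    dplyr::group_by(variable) |>
    dplyr::summarise(present = sum(!is.na(value)), total = dplyr::n())
  masked <- dplyr::count(coh$truth$mask, variable, name = "masked")
  acct <- dplyr::left_join(acct, masked, by = "variable") |>
    dplyr::mutate(masked = dplyr::coalesce(masked, 0L))
  expect_true(all(acct$present + acct$masked == acct$total))
  # masked true values are recoverable and finite
  expect_true(all(is.finite(coh$truth$mask$true_value)))
})

test_that("per-patient channel subsets omit absent devices", {
  cfg <- cohort_config(
    n_patients = 6, duration = 200,
    channels = channel_profiles(),
    channel_presence = c(pbtO2 = 0.5), seed = 13
  )
  coh <- simulate_cohort(cfg)
  with_p <- coh$observations |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(has = "pbtO2" %in% variable)
  expect_true(any(with_p$has) && !all(with_p$has))
  # all patients share the schema for the always-present channels
  expect_true(all(table(coh$observations$variable[coh$observations$variable == "HR"]) > 0))
})

test_that("invalid configurations are rejected", {
  ch <- channel_profiles()[1, ]
  ch$baseline <- 500 # outside HR plausibility
  expect_error(cohort_config(channels = ch), "plausibility")
  expect_error(
    cohort_config(
      channels = channel_profiles(),
      edges = tibble::tibble(
        cause_variable = "HR", cause_state = "HIGH",
        effect_variable = "HR", lag_minutes = 5L, effect_size = 1
      )
    )
  )
  expect_error(
    cohort_config(
      channels = channel_profiles(),
      edges = tibble::tibble(
        cause_variable = "HR", cause_state = "HIGH",
        effect_variable = "MAP", lag_minutes = 0L, effect_size = 1
      )
    )
  )
})
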