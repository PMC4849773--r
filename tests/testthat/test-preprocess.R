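test_that("minute averaging pools observations within half-open minute bins", {
  obs <- tibble::tibble(
    patient_id = "A", variable = "HR",
    timestamp = c(10, 50, 65, 125),
    value = c(80, 84, 95, 70)
  )
  rec <- minute_average(obs)
  expect_equal(rec$value[rec$minute == 0], 82) # mean(80, 84)
  expect_equal(rec$value[rec$minute == 1], 95) # single observation
  expect_equal(rec$value[rec$minute == 2], 70)
  # a minute with no observations is missing
  obs2 <- dplyr::bind_rows(obs, tibble::tibble(
    patient_id = "A", variable = "HR", timestamp = 250, value = 60
  ))
  rec2 <- minute_average(obs2)
  expect_true(is.na(rec2$value[rec2$minute == 3]))
  expect_equal(rec2$status[rec2$minute == 3], "missing")
})

test_that("minute averaging is idempotent on minute-resolution data", {
  withr::with_seed(1, {
    obs <- tibble::tibble(
      patient_id = "A", variable = "HR", timestamp = (0:59) * 60,
      value = rnorm(60, 75, 5)
    )
  })
  rec1 <- minute_average(obs)
  rec2 <- minute_average(
    tibble::tibble(
      patient_id = "A", variable = "HR",
      timestamp = rec1$minute * 60, value = rec1$value
    )
  )
  expect_equal(rec1$value, rec2$value)
})

test_that("minute averaging rejects unknown variables when specs given", {
  obs <- tibble::tibble(
    patient_id = "A", variable = "NOPE", timestamp = 0, value = 1
  )
  expect_error(minute_average(obs, specs = variable_specs()), "unknown")
})

test_that("implausible values are removed, in-bounds values never altered", {
  rec <- tibble::tibble(
    patient_id = "A", variable = c("ICP", "HR", "SPO2"),
    minute = 0L, value = c(250, 70, -5),
    status = "observed"
  )
  out <- suppressMessages(remove_implausible(rec))
  expect_true(is.na(out$value[out$variable == "ICP"])) # 250 outside 0-150
  expect_true(is.na(out$value[out$variable == "SPO2"])) # negative saturation
  expect_equal(out$value[out$variable == "HR"], 70)
  expect_equal(out$status[out$variable == "HR"], "observed")
})

test_that("CPP equals MAP minus ICP with missingness propagation", {
  rec <- tibble::tibble(
    patient_id = "A",
    variable = rep(c("MAP", "ICP"), each = 4),
    minute = rep(0:3, 2),
    value = c(90, 70, NA, 100, 10, 25, 15, NA),
    status = rep(c("observed", "observed", "missing", "observed"), 2)
  )
  out <- derive_cpp(rec)
  cpp <- out[out$variable == "CPP", ]
  expect_equal(cpp$value[1:2], c(80, 45))
  expect_true(all(is.na(cpp$value[3:4])))
  expect_equal(cpp$status[1], "derived")
  expect_equal(cpp$status[3], "missing")
  # a patient without ICP keeps its record, with a warning
  rec2 <- rec[rec$variable == "MAP", ]
  expect_warning(out2 <- derive_cpp(rec2), "absent")
  expect_false("CPP" %in% out2$variable)
})

test_that("CPP identity holds exactly across a simulated record", {
  coh <- simulate_cohort(config_null_cohort(n_patients = 1, duration = 500, seed = 7))
  out <- derive_cpp(coh$observations)
  wide <- out |>
    dplyr::filter(variable %in% c("MAP", "ICP", "CPP")) |>
    tidyr::pivot_wider(
      id_cols = minute, names_from = variable,
      values_from = value
    )
  both <- !is.na(wide$MAP) & !is.na(wide$ICP)
  expect_identical(wide$CPP[both], (wide$MAP - wide$ICP)[both])
})

test_that("phase splitting partitions minutes at the 96-hour boundary", {
  rec <- tibble::tibble(
    patient_id = "A", variable = "HR",
    minute = c(-10L, 0L, 5759L, 5760L, 11519L, 11520L),
    value = 70, status = "observed"
  )
  out <- split_phases(rec, bleed_minute = 0)
  expect_equal(out$phase[out$minute == 0], 1L)
  expect_equal(out$phase[out$minute == 5759], 1L)
  expect_equal(out$phase[out$minute == 5760], 2L) # boundary goes to phase 2
  expect_equal(out$phase[out$minute == 11519], 2L)
  expect_false(any(out$minute %in% c(-10L, 11520L)))
  # every retained minute belongs to exactly one phase
  expect_equal(anyDuplicated(out$minute), 0L)
  # record entirely outside both phases warns
  late <- tibble::tibble(
    patient_id = "A", variable = "HR", minute = 20000L,
    value = 70, status = "observed"
  )
  expect_warning(split_phases(late, 0), "outside")
})

test_that("KPSS statistic matches an independent implementation", {
  # expected statistics computed with statsmodels kpss (regression='c',
  # legacy lag rule) on these exact seeded series
  set.seed(42)
  x1 <- rnorm(300)
  x2 <- cumsum(rnorm(300))
  set.seed(7)
  x3 <- sin(2 * pi * (1:400) / 80) + 0.2 * rnorm(400)
  expect_equal(kpss_test(x1)$statistic, 0.0719563054, tolerance = 1e-8)
  expect_equal(kpss_test(x2)$statistic, 0.5759958100, tolerance = 1e-8)
  expect_equal(kpss_test(x3)$statistic, 0.0979115843, tolerance = 1e-8)
  expect_equal(kpss_test(x1)$p_value, 0.10)
  expect_lt(kpss_test(x2)$p_value, 0.05)
})

test_that("data characteristics: constant, half-present and short channels", {
  rec <- dplyr::bind_rows(
    tibble::tibble(
      patient_id = "A", variable = "TMP", minute = 0:199,
      value = 37, status = "observed"
    ),
    tibble::tibble(
      patient_id = "A", variable = "HR", minute = 0:199,
      value = ifelse(0:199 < 100, 75, NA),
      status = ifelse(0:199 < 100, "observed", "missing")
    ),
    tibble::tibble(
      patient_id = "A", variable = "ICP", minute = 0:199,
      value = ifelse(0:199 < 10, 12, NA),
      status = ifelse(0:199 < 10, "observed", "missing")
    )
  )
  ch <- data_characteristics(rec)
  tmp <- ch[ch$variable == "TMP", ]
  expect_equal(tmp$sd_percent, 0)
  expect_false(tmp$nonstationary) # constant: KPSS does not reject
  expect_equal(ch$availability_percent[ch$variable == "HR"], 50)
  # under 30 observed minutes: metrics undefined
  expect_true(is.na(ch$sd_percent[ch$variable == "ICP"]))
  coh <- cohort_characteristics(ch)
  expect_equal(coh$nonstationary_fraction[coh$variable == "TMP"], 0)
})

test_that("drifting channels are flagged nonstationary at cohort level", {
  recs <- lapply(1:5, function(i) {
    withr::with_seed(200 + i, {
      tibble::tibble(
        patient_id = sprintf("P%d", i), variable = "ICP", minute = 0:1999,
        value = cumsum(rnorm(2000)), status = "observed"
      )
    })
  })
  ch <- data_characteristics(dplyr::bind_rows(recs))
  frac <- cohort_characteristics(ch)$nonstationary_fraction
  expect_gte(frac, 0.8)
})
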