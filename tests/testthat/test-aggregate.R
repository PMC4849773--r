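make_models <- function() {
  tibble::tibble(
    patient_id = c("P1", "P2", "P3", "P1"),
    phase = 1L,
    cause_variable = c("ICP", "ICP", "ICP", "MAP"),
    cause_state = c("HIGH", "HIGH", "HIGH", "LOW"),
    effect = c("HR", "HR", "HR", "HR"),
    r = 6L, s = 10L,
    epsilon = c(0.5, 0.4, -0.3, 0.2),
    n_cause = 50, n_conditioning = 2,
    z = 3, p = 0.01, significant = TRUE,
    sign = c("INCREASE", "INCREASE", "DECREASE", "INCREASE"),
    null_method = "empirical"
  )
}

make_measured <- function() {
  tidyr::expand_grid(
    patient_id = c("P1", "P2", "P3", "P4"),
    variable = c("ICP", "HR", "MAP")
  ) |>
    dplyr::mutate(measured = !(patient_id == "P4" & variable == "ICP"))
}

test_that("population summaries count patients against measuring denominators", {
  s <- summarize_population(make_models(), make_measured())
  icp <- s[s$cause_variable == "ICP", ]
  expect_equal(icp$n_significant, 3L)
  expect_equal(icp$n_measured, 3L) # P4 does not measure ICP
  expect_equal(icp$percent, 100)
  expect_equal(icp$n_increase, 2L)
  expect_equal(icp$n_decrease, 1L)
  map <- s[s$cause_variable == "MAP", ]
  expect_equal(map$n_measured, 4L)
  expect_equal(map$percent, 25) # 1 of 4 measuring patients
  # empty model list -> empty summary
  empty <- summarize_population(make_models()[0, ], make_measured())
  expect_equal(nrow(empty), 0L)
})

test_that("population summaries are invariant to patient order", {
  m <- make_models()
  s1 <- summarize_population(m, make_measured())
  s2 <- summarize_population(m[c(4, 2, 1, 3), ], make_measured())
  expect_equal(
    dplyr::arrange(s1, cause_variable),
    dplyr::arrange(s2, cause_variable)
  )
})

test_that("graph export filters by percent and keeps opposing edges", {
  m <- dplyr::bind_rows(
    make_models(),
    tibble::tibble(
      patient_id = "P2", phase = 1L, cause_variable = "HR",
      cause_state = "HIGH", effect = "ICP", r = 6L, s = 10L,
      epsilon = 0.3, n_cause = 40, n_conditioning = 1, z = 3, p = 0.01,
      significant = TRUE, sign = "INCREASE", null_method = "empirical"
    )
  )
  s <- summarize_population(m, make_measured(), collapse_windows = TRUE)
  g <- export_graph(s, min_percent = 0)
  # ICP -> HR and HR -> ICP both present as directed edges
  expect_true(any(g$from == "ICP" & g$to == "HR"))
  expect_true(any(g$from == "HR" & g$to == "ICP"))
  expect_equal(g$dominant_sign[g$from == "ICP" & g$to == "HR"], "INCREASE")
  g60 <- export_graph(s, min_percent = 60)
  expect_true(all(g60$percent >= 60))
  expect_equal(nrow(export_graph(s[0, ], 0)), 0L)
})

test_that("recovery scoring matches planted structure bookkeeping", {
  models <- make_models()
  edges <- tibble::tibble(
    cause_variable = "ICP", cause_state = "HIGH", effect_variable = "HR",
    lag_minutes = 8L, effect_size = 12, duration_minutes = 5L
  )
  sc <- score_recovery(models, make_measured(), edges, call_threshold = 30)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
  expect_true(sc$window_consistent == 1) # lag 8 inside window [6,10]
  expect_true(sc$sign_consistent == 1)
  # an unplanted called pair drops precision
  edges2 <- edges
  edges2$cause_variable <- "CVP" # planted elsewhere; ICP->HR now false
  sc2 <- score_recovery(models, make_measured(), edges2, call_threshold = 30)
  expect_equal(sc2$recall, 0)
  expect_lt(sc2$precision, 1)
})

test_that("gap statistic results are seeded and reproducible", {
  x <- withr::with_seed(2, matrix(rnorm(80), ncol = 2))
  g1 <- gap_kmeans(x, k_max = 4, B = 50, seed = 5)
  g2 <- gap_kmeans(x, k_max = 4, B = 50, seed = 5)
  expect_equal(g1$gap_curve, g2$gap_curve)
  expect_equal(g1$k, g2$k)
  expect_s3_class(tidy(g1), "tbl_df")
  expect_equal(nrow(tidy(g1)), 40L)
  expect_equal(glance(g1)$k, g1$k)
})

test_that("k_max is reduced when the cohort is too small", {
  x <- matrix(rnorm(10), ncol = 2)
  expect_warning(g <- gap_kmeans(x, k_max = 8, B = 20, seed = 1), "k_max")
  expect_lte(g$k, 4)
})

test_that("patients sharing a relationship in one tight cluster score small p", {
  withr::with_seed(64, {
    centers <- matrix(c(0, 0, 8, 8), ncol = 2, byrow = TRUE)
    x <- centers[rep(1:2, each = 15), ] + matrix(rnorm(60, sd = 0.5), ncol = 2)
  })
  rownames(x) <- sprintf("P%02d", 1:30)
  rel <- list(
    clustered = sprintf("P%02d", 1:10), # all from the tight first cluster
    tiny = sprintf("P%02d", 1:2) # below the support rule
  )
  out <- relationship_cluster_test(x, rel, n_perm = 500, seed = 3)
  expect_lt(out$p_value[out$relationship == "clustered"], 0.05)
  expect_true(is.na(out$p_value[out$relationship == "tiny"]))
})

test_that("random relationships give uniform cluster-test p-values", {
  withr::with_seed(65, {
    x <- matrix(rnorm(60), ncol = 2)
  })
  rownames(x) <- sprintf("P%02d", 1:30)
  ps <- sapply(1:20, function(i) {
    pats <- withr::with_seed(1000 + i, sample(rownames(x), 8))
    relationship_cluster_test(x, list(r = pats), n_perm = 400, seed = i)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort objects expose tidy and glance views", {
  coh <- simulate_cohort(config_null_cohort(n_patients = 2, duration = 200, seed = 1))
  expect_identical(tidy(coh), coh$observations)
  g <- glance(coh)
  expect_equal(g$n_patients, 2L)
  expect_equal(g$n_planted_edges, 0L)
  expect_output(print(coh), "synthetic cohort")
})

test_that("plot builders return ggplot objects", {
  coh <- simulate_cohort(config_null_cohort(n_patients = 1, duration = 300, seed = 2))
  ch <- data_characteristics(coh$observations)
  expect_s3_class(plot_characteristics(ch), "ggplot")
  s <- summarize_population(make_models(), make_measured(), collapse_windows = TRUE)
  expect_s3_class(plot_summary(s), "ggplot")
  x <- withr::with_seed(2, matrix(rnorm(80), ncol = 2))
  g <- gap_kmeans(x, k_max = 3, B = 20, seed = 5)
  expect_s3_class(ggplot2::autoplot(g), "ggplot")
})
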