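test_that("the duration sampler hits its exceedance targets", {
  set.seed(91)
  targets <- c(0.85, 0.70, 0.40, 0.15)
  d <- sample_sf_durations(4e4, c(3, 6, 12, 24), targets)
  emp <- vapply(c(3, 6, 12, 24), function(t) mean(d >= t), numeric(1))
  expect_equal(emp, targets, tolerance = 0.02)

  # a saturated first threshold (everyone reaches 3 months) is legal
  d2 <- sample_sf_durations(5e3, c(3, 6, 12, 24), c(1, 0.9, 0.7, 0.5))
  expect_equal(mean(d2 >= 3), 1)

  expect_error(sample_sf_durations(10, c(3, 6), c(0.4, 0.6)),
               "infeasible exceedance")
  cfg <- asthma_cohort_config()
  expect_error(
    cohort_config(cfg$subgroups, cfg$state_shares, cfg$cost_moments,
                  dplyr::mutate(cfg$duration_targets,
                                exceedance = rev(exceedance))),
    "infeasible exceedance")
})

test_that("cohort generation is reproducible and respects the config shape", {
  cfg <- asthma_cohort_config(seed = 17)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$visits, c2$visits)

  expect_equal(nrow(c1$patients), 8 + 22 + 21 + 8)
  expect_equal(sum(c1$patients$n_visits), nrow(c1$visits))
  expect_true(all(c1$patients$n_visits >= 1))
  expect_true(all(c1$patients$longest_symptom_free <=
                    c1$patients$followup_months))
  costs <- c1$visits[c("ics_cost", "tcm_cost", "other_cost",
                       "non_medication_cost")]
  expect_true(all(as.matrix(costs) >= 0))

  c3 <- generate_cohort(asthma_cohort_config(seed = 18))
  expect_false(identical(c1$visits$ics_cost, c3$visits$ics_cost))
})

test_that("a minimal single-patient cohort generates one valid record", {
  cfg <- cohort_config(
    subgroups = tibble::tibble(strategy = "X", n_patients = 1,
                               visit_mean = 1, visit_sd = 0.9,
                               followup_mean = 12, followup_sd = 3),
    state_shares = tibble::tibble(strategy = "X", state = health_states(),
                                  probability = c(0.2, 0.3, 0.5)),
    cost_moments = tidyr::expand_grid(
      strategy = "X", state = health_states(),
      category = c("ics", "tcm", "other", "non_medication")) |>
      dplyr::mutate(mean = 100, sd = 20),
    duration_targets = tibble::tibble(strategy = "X",
                                      threshold_months = c(3, 6, 12, 24),
                                      exceedance = c(0.8, 0.6, 0.3, 0.1)),
    seed = 5
  )
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort$patients), 1)
  expect_gte(nrow(cohort$visits), 1)
})

test_that("aggregation mirrors the study's own reduction of its records", {
  cohort <- generate_cohort(asthma_cohort_config(seed = 23))
  summ <- aggregate_cohort(cohort)
  expect_s3_class(summ$strategies_ics, "strategy_params")
  expect_s3_class(summ$strategies_medication, "strategy_params")

  # probabilities are visit shares recomputed from the generated records
  brute <- table(cohort$visits$strategy, cohort$visits$state)
  for (s in unique(cohort$visits$strategy)) {
    p <- summ$strategies_ics$probability[summ$strategies_ics$strategy == s]
    expect_equal(p, as.numeric(brute[s, health_states()] / sum(brute[s, ])))
  }

  # effectiveness is monotone on every generated cohort
  mono <- dplyr::summarise(
    dplyr::group_by(summ$effectiveness, strategy),
    ok = all(diff(rate_percent) <= 0))
  expect_true(all(mono$ok))

  # medication basis equals ICS + TCM + other per state
  v <- cohort$visits
  med <- tapply(v$ics_cost + v$tcm_cost + v$other_cost,
                list(v$strategy, v$state), mean)
  tab <- summ$strategies_medication
  for (s in rownames(med)) {
    got <- tab$cost_cny[tab$strategy == s]
    expect_equal(got, as.numeric(med[s, health_states()]))
  }
})

test_that("a state with no visits aggregates to probability zero", {
  cfg <- cohort_config(
    subgroups = tibble::tibble(strategy = "X", n_patients = 30,
                               visit_mean = 4, visit_sd = 3,
                               followup_mean = 12, followup_sd = 3),
    state_shares = tibble::tibble(strategy = "X", state = health_states(),
                                  probability = c(0, 0.3, 0.7)),
    cost_moments = tidyr::expand_grid(
      strategy = "X", state = health_states(),
      category = c("ics", "tcm", "other", "non_medication")) |>
      dplyr::mutate(mean = 100, sd = 20),
    duration_targets = tibble::tibble(strategy = "X",
                                      threshold_months = c(3, 6, 12, 24),
                                      exceedance = c(0.8, 0.6, 0.3, 0.1)),
    seed = 6
  )
  summ <- aggregate_cohort(generate_cohort(cfg))
  hosp <- summ$strategies_ics[summ$strategies_ics$state == "hospitalization", ]
  expect_equal(hosp$probability, 0)
  expect_equal(hosp$cost_cny, 0)
  expect_false("hospitalization" %in% summ$cost_summary$state)
})

test_that("aggregated parameters recover the configured generating process", {
  # moderate n here; the full-scale recovery check lives with the
  # acceptance properties
  cfg <- asthma_cohort_config(n_patients = 2000, seed = 29)
  summ <- aggregate_cohort(generate_cohort(cfg))

  shares <- dplyr::inner_join(
    summ$strategies_ics[c("strategy", "state", "probability")],
    cfg$state_shares, by = c("strategy", "state"),
    suffix = c("_got", "_want"))
  expect_lt(max(abs(shares$probability_got - shares$probability_want)), 0.02)

  # expected values from the recovered table converge to the closed form
  # implied by the configured shares and cost means
  res <- evaluate_strategy(summ$strategies_ics)
  want <- dplyr::inner_join(
    cfg$state_shares,
    dplyr::filter(cfg$cost_moments, category == "ics"),
    by = c("strategy", "state"))
  want <- dplyr::summarise(dplyr::group_by(want, strategy),
                           ec = sum(probability * mean), .groups = "drop")
  both <- dplyr::inner_join(res, want, by = "strategy")
  expect_equal(both$expected_cost, both$ec, tolerance = 0.1)
})

test_that("cohorts round-trip through CSV", {
  cohort <- generate_cohort(asthma_cohort_config(seed = 3))
  dir <- withr::local_tempdir()
  write_cohort_csv(cohort, dir)
  back <- readr::read_csv(file.path(dir, "patients.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(cohort$patients))
  expect_equal(back$longest_symptom_free, cohort$patients$longest_symptom_free)
})
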