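test_that("gamma moment fit is exact in both directions", {
  g <- fit_gamma_from_moments(100, 10)
  expect_equal(g$shape, 100)
  expect_equal(g$scale, 1)

  # Moments printed for a hospital medication cost: mean 1982.34, sd 1863.04
  g2 <- fit_gamma_from_moments(1982.34, 1863.04)
  expect_equal(g2$shape, (1982.34 / 1863.04)^2)
  # round trip: analytic moments of the fitted distribution
  expect_equal(g2$shape * g2$scale, 1982.34)
  expect_equal(sqrt(g2$shape) * g2$scale, 1863.04)

  expect_error(fit_gamma_from_moments(-1, 10), "positive")
  expect_error(fit_gamma_from_moments(10, 0), "positive")
})

test_that("sampled gamma mean converges to the fitted mean", {
  g <- fit_gamma_from_moments(1982.34, 1863.04)
  set.seed(71)
  x <- rgamma(2e5, shape = g$shape, scale = g$scale)
  expect_equal(mean(x), 1982.34, tolerance = 0.01)
})

test_that("dirichlet priors have the right moments", {
  d <- dirichlet_from_counts(c(8, 8, 30))
  expect_equal(round(d$mean, 4), c(0.1739, 0.1739, 0.6522))
  expect_equal(dirichlet_from_counts(c(1, 1, 1))$mean, rep(1 / 3, 3))
  expect_error(dirichlet_from_counts(c(0, 3, 4)), "zero count")

  set.seed(72)
  alpha <- c(8, 8, 30)
  draws <- rdirichlet(1e5, alpha)
  expect_equal(rowSums(draws), rep(1, 1e5))
  n0 <- sum(alpha)
  for (i in 1:3) {
    beta_sd <- sqrt(alpha[i] * (n0 - alpha[i]) / (n0^2 * (n0 + 1)))
    expect_equal(sd(draws[, i]), beta_sd, tolerance = 0.02)
    expect_equal(mean(draws[, i]), alpha[i] / n0, tolerance = 0.02)
  }
})

test_that("a fully degenerate PSA returns the base case in every draw", {
  params <- asthma_strategies("ics")
  zero_sd <- tibble::tibble(state = health_states(), sd = 0)
  ref <- psa_spec(params, "A", cost_sd = zero_sd)
  alt <- psa_spec(params, "B", cost_sd = zero_sd)
  psa <- run_psa(ref, alt, n = 50, seed = 9)
  expect_equal(psa$draws$delta_cost, rep(psa$base$delta_cost, 50))
  expect_equal(psa$draws$delta_utility, rep(psa$base$delta_utility, 50))
})

test_that("seeded PSA runs are bit-reproducible and basis-checked", {
  ref <- asthma_psa_spec("A", "medication")
  alt <- asthma_psa_spec("B", "medication")
  p1 <- run_psa(ref, alt, n = 200, seed = 123)
  p2 <- run_psa(ref, alt, n = 200, seed = 123)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(ref, alt, n = 200, seed = 124)
  expect_false(identical(p1$draws$delta_cost, p3$draws$delta_cost))

  expect_error(run_psa(asthma_psa_spec("A", "ics"), alt, n = 10),
               "cost basis mismatch")
})

test_that("PSA draws center on the deterministic incremental utility", {
  ref <- asthma_psa_spec("A", "medication")
  alt <- asthma_psa_spec("B", "medication")
  psa <- run_psa(ref, alt, n = 1000, seed = 7)
  # printed incremental utility for the pooled comparison is 0.47 QALYs
  expect_equal(mean(psa$draws$delta_utility), 0.47, tolerance = 0.05)
  expect_equal(psa$base$delta_utility, 0.47, tolerance = 0.01)
})

test_that("PSA error shrinks with the number of iterations", {
  ref <- asthma_psa_spec("A", "ics")
  alt <- asthma_psa_spec("B", "ics")
  err_at <- function(n) {
    e <- vapply(1:15, function(s) {
      p <- run_psa(ref, alt, n = n, seed = s)
      mean(p$draws$delta_cost) - p$base$delta_cost
    }, numeric(1))
    sqrt(mean(e^2))
  }
  rmse_small <- err_at(60)
  rmse_big <- err_at(960)   # 16x the iterations: expect ~4x smaller RMSE
  expect_lt(rmse_big, rmse_small / 1.5)
})

test_that("the CEAC matches its closed-form endpoints and hand example", {
  two <- tibble::tibble(delta_cost = c(-1, 1), delta_utility = c(0.1, 0.1))
  expect_equal(ceac(two, wtp_grid = 5)$prob_cost_effective, 0.5)

  ref <- asthma_psa_spec("A", "ics")
  alt <- asthma_psa_spec("B", "ics")
  psa <- run_psa(ref, alt, n = 500, seed = 3)
  curve <- ceac(psa, wtp_grid = c(0, 1e9))
  expect_equal(curve$prob_cost_effective[1], mean(psa$draws$delta_cost < 0))
  expect_equal(curve$prob_cost_effective[2],
               mean(psa$draws$delta_utility > 0))

  # non-decreasing in lambda when every draw gains utility
  stopifnot(all(psa$draws$delta_utility > 0))
  mono <- ceac(psa, wtp_grid = seq(0, 5e5, by = 2.5e4))
  expect_true(all(diff(mono$prob_cost_effective) >= 0))

  expect_error(ceac(psa, wtp_grid = numeric(0)), "empty WTP grid")
})

test_that("the confidence ellipse has normal-theory coverage", {
  set.seed(81)
  n <- 1e4
  z1 <- rnorm(n); z2 <- rnorm(n)
  draws <- tibble::tibble(delta_cost = 100 + 50 * z1,
                          delta_utility = 0.5 + 0.1 * (0.6 * z1 + 0.8 * z2))
  summ <- ce_plane_summary(draws, level = 0.95)
  expect_equal(summ$inside_fraction, 0.95, tolerance = 0.015)
  expect_equal(sum(summ$quadrants$share), 1)

  # degenerate cloud collapses to a point with full coverage
  fixed <- tibble::tibble(delta_cost = rep(1, 5), delta_utility = rep(2, 5))
  expect_warning(point <- ce_plane_summary(fixed), "point")
  expect_equal(point$inside_fraction, 1)
})

test_that("PSA plots build without error", {
  ref <- asthma_psa_spec("A", "ics")
  alt <- asthma_psa_spec("B", "ics")
  psa <- run_psa(ref, alt, n = 100, seed = 2)
  p1 <- autoplot(psa)
  expect_s3_class(p1, "ggplot")
  p2 <- autoplot(ceac(psa), wtp = 287100)
  expect_s3_class(p2, "ggplot")
  g <- glance(psa)
  expect_equal(g$n_iterations, 100)
  expect_equal(nrow(tidy(psa)), 100)
})
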