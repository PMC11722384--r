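test_that("population construction tiles the circle", {
  expect_length(build_population(10)$preferred, 36)
  expect_equal(build_population(90)$preferred, c(0, 90, 180, 270))
  expect_error(build_population(7), "divide")
})

test_that("gain draws collapse to the mean profile without heterogeneity", {
  pop <- build_population()
  gm0 <- gain_model(heterogeneity_sd = 0)
  g <- draw_gains(pop, 40, gm0)
  expect_equal(g[pop$preferred == 40], gm0$gain_aligned)
  expect_equal(g[pop$preferred == 220], gm0$gain_opposed)
  # antipodal centers give mirror-image gain vectors
  g2 <- draw_gains(pop, 220, gm0)
  mirror <- match((pop$preferred + 180) %% 360, pop$preferred)
  expect_equal(g, g2[mirror])
})

test_that("gain acts multiplicatively on the tuned component", {
  pop <- build_population(90, baseline_rate = 2, amplitude = 8)
  m <- simulate_mean_responses(pop, cbind(rep(1.3, 4), rep(0.8, 4)),
                               directions = c(0, 90, 180, 270))
  # peak (above baseline) ratio between conditions at the preferred dir
  expect_equal((m[1, 1, 1] - 2) / (m[1, 2, 1] - 2), 1.3 / 0.8)
  # gain = 1 in both conditions leaves no reward signal
  m1 <- simulate_mean_responses(pop, cbind(rep(1, 4), rep(1, 4)),
                                directions = c(0, 90, 180, 270))
  expect_equal(m1[, 1, ], m1[, 2, ])
})

test_that("single-unit tuning is seed-invariant while the formatting angle is not", {
  pop <- build_population()
  thetas <- vapply(1:8, function(s) {
    g <- draw_condition_gains(pop, seed = s)
    means <- simulate_mean_responses(pop, g)
    formatting_angle(means)$theta_deg
  }, numeric(1))
  expect_gt(diff(range(thetas)), 5)   # population formatting varies by draw
  # tuning parameters (preferred directions, curve shape) never vary
  expect_identical(build_population()$preferred, pop$preferred)
  tc1 <- popformat:::tuning_curve(pop, seq(0, 350, 10))
  expect_identical(popformat:::tuning_curve(build_population(),
                                            seq(0, 350, 10)), tc1)
})

test_that("the formatting angle is invariant to joint rotation of the task", {
  pop <- build_population()
  gm <- gain_model(heterogeneity_sd = 0)
  th <- vapply(c(0, 40, 160), function(rot) {
    g <- cbind(draw_gains(pop, 45 + rot, gm), draw_gains(pop, 225 + rot, gm))
    formatting_angle(simulate_mean_responses(pop, g))$theta_deg
  }, numeric(1))
  expect_lt(diff(range(th)), 1e-6)
})

test_that("orthogonalized coordination produces a separable geometry", {
  pop <- build_population()
  g <- draw_condition_gains(pop, gm = gain_model(
    coordination = "orthogonalized"), seed = 4)
  means <- simulate_mean_responses(pop, g)
  expect_gt(formatting_angle(means)$theta_deg, 85)
})

test_that("heterogeneity draws span separable and joint regimes", {
  sw <- tuning_theta_sweep(50, seed = 101)
  expect_equal(nrow(sw), 50)
  expect_gt(sum(sw$theta_deg > 70), 0)
  expect_gt(sum(sw$theta_deg < 45), 0)
})
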