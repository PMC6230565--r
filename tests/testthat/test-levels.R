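test_that("each phase starts exactly at its start level", {
  cp <- cp_default()
  set.seed(21)
  for (i in 1:10) {
    hp <- random_params()
    t0 <- runif(1, 0, 24)
    s_b <- runif(1, hp$wake_threshold, hp$sleep_threshold)
    s_d <- runif(1, hp$wake_threshold, hp$sleep_threshold)
    expect_identical(buildup_level(t0, t0, s_b, cp, hp), s_b)
    expect_identical(decay_level(t0, t0, s_d, cp, hp), s_d)
  }
})

test_that("zero-amplitude levels follow the plain exponentials", {
  cp <- cp_zero()
  hp <- homeostat_params()      # Xu = 5, Xb = 0.755, Xd = 2.75, Xl = 0.70
  # closed-form value after 17.65 h of buildup from the wake threshold
  dt_b <- 17.65
  expect_equal(buildup_level(10 + dt_b, 10, 0.755, cp, hp),
               5 - (5 - 0.755) * exp(-dt_b / 27.81), tolerance = 1e-12)
  expect_equal(buildup_level(10 + dt_b, 10, 0.755, cp, hp), 2.75,
               tolerance = 1e-3)
  # closed-form value after 8.68 h of decay from the sleep-onset threshold
  dt_d <- 8.68
  expect_equal(decay_level(23 + dt_d, 23, 2.75, cp, hp),
               0.70 + (2.75 - 0.70) * exp(-dt_d / 2.40), tolerance = 1e-12)
  expect_equal(decay_level(23 + dt_d, 23, 2.75, cp, hp), 0.755,
               tolerance = 1e-3)
  # asymptotes
  expect_equal(buildup_level(10 + 500, 10, 0.755, cp, hp), 5, tolerance = 1e-7)
  expect_equal(decay_level(23 + 200, 23, 2.75, cp, hp), 0.70, tolerance = 1e-7)
  # monotone decay toward the lower asymptote
  tt <- seq(23, 33, by = 0.1)
  expect_true(all(diff(decay_level(tt, 23, 2.75, cp, hp)) < 0))
})

test_that("a circadian gain that exhausts the time constant is rejected", {
  cp <- circadian_params(amplitude = 0.5, modulation_gain = 2)
  hp_bad <- homeostat_params(decay_constant = 0.8)   # T_d - k*C can reach -0.2
  expect_error(decay_level(seq(0, 24, 0.5), 0, 2.75, cp, hp_bad),
               "non-positive effective time constant")
  # the buildup constant is large enough to stay positive
  expect_silent(buildup_level(seq(0, 24, 0.5), 0, 0.755, cp, hp_bad))
})

test_that("simulated levels stay inside the modulated envelope", {
  for (label in c("<=6", "16+")) {
    g <- age_group_params(label)
    tr <- swa_trajectory(default_schedule_sim(label), dt = 0.02)
    A <- g$circadian$amplitude
    expect_true(all(tr$swa_level >= g$homeostat$lower_asymptote - A - 1e-9))
    expect_true(all(tr$swa_level <= g$homeostat$upper_asymptote + A + 1e-9))
  }
})
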