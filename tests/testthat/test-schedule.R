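test_that("forced mornings wake exactly at the alarm", {
  sim <- default_schedule_sim("12+")
  forced <- sim$days[sim$days$day_type == "forced", ]
  expect_equal(forced$risetime, rep(6.70, nrow(forced)))
  expect_equal(sim$days$time_in_bed,
               (sim$days$risetime - sim$days$bedtime) %% 24,
               tolerance = 1e-9)
})

test_that("an alarm at the free-running risetime changes nothing", {
  g <- age_group_params("10+")
  fr <- simulate_free_run(g$circadian, g$homeostat,
                          init_risetime = g$free_risetime)
  sim <- simulate_schedule(g$circadian, g$homeostat,
                           schedule = schedule_spec(fr$risetime, fr$risetime,
                                                    weeks = 2))
  tail_days <- utils::tail(sim$days, 7)
  expect_equal(tail_days$bedtime, rep(fr$bedtime, 7), tolerance = 1e-3)
  expect_equal(tail_days$risetime %% 24, rep(fr$risetime, 7), tolerance = 1e-3)
})

test_that("sleep restriction pulls school-night bedtimes earlier", {
  g <- age_group_params("15+")
  fr <- simulate_free_run(g$circadian, g$homeostat,
                          init_risetime = g$free_risetime)
  sim <- default_schedule_sim("15+")
  wk <- utils::tail(sim$days, 7)
  school_beds <- wk$bedtime[1:5]      # Sun-Thu nights, alarm-truncated sleep
  expect_true(all(school_beds < fr$bedtime))
  # Friday night starts earlier than Saturday night, hence the longer
  # Friday-Saturday sleep
  expect_lt(wk$bedtime[6], wk$bedtime[7])
  expect_gt(wk$time_in_bed[6], mean(wk$time_in_bed[1:5]))
})

test_that("the schedule reaches a steady week after the burn-in", {
  sim <- default_schedule_sim("16+", weeks = 3)
  d <- sim$days
  n <- nrow(d)
  last <- d[(n - 6):n, ]
  prev <- d[(n - 13):(n - 7), ]
  expect_equal(last$bedtime, prev$bedtime, tolerance = 1e-3)
  expect_equal(last$risetime, prev$risetime, tolerance = 1e-3)
})

test_that("waking pressure never exceeds the sleep-onset set point", {
  for (label in c("12+", "18+")) {
    sim <- default_schedule_sim(label)
    tr <- swa_trajectory(sim, dt = 0.02)
    wake <- tr[tr$phase == "buildup", ]
    thr <- switch_threshold("buildup", wake$time_h, sim$cp, sim$hp, sim$rule)
    expect_true(all(wake$swa_level <= thr + 1e-4))
  }
})

test_that("the pre-alarm SWA level is nearly flat across the steady week", {
  sim <- default_schedule_sim("16+", weeks = 2)
  prof <- swa_at_alarm_profile(sim)
  steady <- utils::tail(prof, 7)
  expect_lt(max(steady$swa_level) - min(steady$swa_level), 0.25)
  # an undisturbed (all-free) schedule gives the same level every day
  g <- age_group_params("16+")
  free_spec <- schedule_spec(g$free_risetime, g$weekday_alarm,
                             day_sequence = rep("free", 12))
  free_sim <- simulate_schedule(g$circadian, g$homeostat, schedule = free_spec)
  free_prof <- swa_at_alarm_profile(free_sim)
  lv <- utils::tail(free_prof$swa_level, 4)
  expect_lt(max(lv) - min(lv), 1e-3)
})

test_that("week summaries implement the reporting conventions", {
  sim <- default_schedule_sim("18+")
  ws <- summarize_week(sim)
  wk <- utils::tail(sim$days, 7)
  expect_equal(ws$weekday_bedtime, mean(wk$bedtime[2:6]))
  expect_equal(ws$weekend_bedtime, wk$bedtime[7])
  expect_equal(ws$weekend_risetime, mean(wk$risetime[6:7]))
  expect_equal(ws$weekday_risetime, 7.70)
  expect_equal(ws$weekday_tib, (7.70 - ws$weekday_bedtime) %% 24)
  expect_equal(ws$shift_bedtime, ws$weekday_bedtime - ws$weekend_bedtime)
  # alternative school-night convention averages the Sun-Thu nights instead
  ws2 <- summarize_week(sim, aggregation = list(weekday_nights = "school"))
  expect_equal(ws2$weekday_bedtime, mean(wk$bedtime[1:5]))
  # too short a schedule is refused
  short <- sim
  short$days <- sim$days[1:5, ]
  expect_error(summarize_week(short), "too short")
})
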