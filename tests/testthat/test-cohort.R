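make_sample <- function(id, age, n = 100, method = "survey",
                        times = c(22.23, 6.71, 23.47, 9.25)) {
  data.frame(sample_id = id, mean_age = age, n_subjects = n,
             method = method, chronotype = "all",
             weekday_bedtime = times[1], weekday_risetime = times[2],
             weekend_bedtime = times[3], weekend_risetime = times[4],
             stringsAsFactors = FALSE)
}

test_that("age binning uses left-open right-closed printed boundaries", {
  s <- rbind(make_sample("a", 5.9), make_sample("b", 6.0),
             make_sample("c", 6.01), make_sample("d", 10.0),
             make_sample("e", 17.9), make_sample("f", 23.4))
  b <- bin_samples(s)
  expect_equal(as.character(b$group_label),
               c("<=6", "<=6", "6+", "6+", "16+", "18+"))
  # empty input gives empty bins, not an error
  empty <- bin_samples(s[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(levels(empty$group_label), age_group_labels())
  expect_error(bin_samples(s, bin_edges = c(10, 6)), "increasing")
})

test_that("synthetic cohorts recover the configured bin occupancy", {
  sizes <- c(16, 21, 24, 25, 14, 21, 21, 18)
  coh <- generate_cohort(synth_config(seed = 7))
  counts <- table(bin_samples(coh)$group_label)
  expect_equal(as.numeric(counts), sizes)
  expect_equal(sum(sizes), 160)
})

test_that("group summaries average samples with Student-t intervals", {
  # identical samples: mean equals the sample, interval collapses
  s <- do.call(rbind, lapply(1:4, function(i)
    make_sample(paste0("s", i), 12.5, times = c(20.42, 7.26, 20.89, 7.88))))
  g <- summarize_group(s)
  expect_equal(g$weekday_bedtime, 20.42)
  expect_equal(g$weekend_risetime, 7.88)
  expect_equal(g$weekend_bedtime_ci, 0)
  # a single sample has no interval
  expect_warning(g1 <- summarize_group(s[1, ]), "CI undefined")
  expect_true(is.na(g1$weekday_bedtime_ci))
  # subject-weighted mean on a two-sample toy, against hand arithmetic
  s2 <- rbind(make_sample("x", 12.5, n = 1, times = c(22, 7, 23, 9)),
              make_sample("y", 12.5, n = 3, times = c(23, 7, 24, 9)))
  gw <- summarize_group(s2, weighting = "n_subjects")
  expect_equal(gw$weekday_bedtime, (1 * 22 + 3 * 23) / 4)
  # interval half-width matches the t-based formula
  s3 <- rbind(make_sample("p", 12.5, times = c(22, 7, 23, 9)),
              make_sample("q", 12.5, times = c(23, 7, 24, 9)),
              make_sample("r", 12.5, times = c(24, 7, 25, 9)))
  g3 <- summarize_group(s3)
  expect_equal(g3$weekday_bedtime_ci, qt(0.975, 2) * sd(22:24) / sqrt(3))
})

test_that("times in bed come from modular subtraction of the aggregates", {
  emp <- empirical_sleep_times()
  row18 <- emp[emp$group_label == "18+", ]
  s <- make_sample("t", 20,
                   times = c(row18$weekday_bedtime, row18$weekday_risetime,
                             row18$weekend_bedtime, row18$weekend_risetime))
  g <- suppressWarnings(summarize_group(s))
  expect_equal(g$weekday_tib, 7.41)    # (7.66 - 24.25) mod 24
  expect_equal(g$weekend_tib, 8.38)    # (9.80 - 25.42) mod 24
})

test_that("discrepancies are antisymmetric and vanish on identical inputs", {
  sim <- do.call(rbind, lapply(c("12+", "18+"), simulate_age_group))
  d0 <- discrepancy_table(sim, sim)
  expect_true(all(d0$discrepancy == 0))
  emp <- empirical_sleep_times()
  emp <- emp[emp$group_label %in% c("12+", "18+"), ]
  d1 <- discrepancy_table(emp, sim)
  d2 <- discrepancy_table(sim, emp)
  expect_equal(d1$discrepancy, -d2$discrepancy, tolerance = 1e-12)
  # misaligned groups are refused
  expect_error(discrepancy_table(emp[1, ], sim), "same group labels")
})

test_that("cohort-level weekday sleep loss is the n-weighted mean", {
  toy <- data.frame(group_label = age_group_labels(),
                    weekday_tib = rep(8, 8), weekend_tib = rep(8, 8),
                    n_samples = rep(1, 8))
  expect_equal(weekday_sleep_loss(toy), 0)
  toy$weekend_tib <- 8 + c(1, 2, rep(1.5, 6))
  toy$n_samples <- c(1, 3, rep(0.0001, 6))
  expect_equal(weekday_sleep_loss(toy), 1.75, tolerance = 1e-3)
  expect_error(weekday_sleep_loss(toy[1:3, ]), "incomplete cohort")
})
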