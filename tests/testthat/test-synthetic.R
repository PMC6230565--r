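test_that("the generator is deterministic given its seed", {
  c1 <- generate_cohort(synth_config(seed = 123))
  c2 <- generate_cohort(synth_config(seed = 123))
  expect_identical(c1, c2)
  c3 <- generate_cohort(synth_config(seed = 124))
  expect_false(identical(c1, c3))
})

test_that("a noise-free cohort reproduces the anchors exactly", {
  cfg <- synth_config(noise_sd = 0, seed = 5)
  coh <- generate_cohort(cfg)
  summ <- summarize_cohort(coh)
  anchors <- cfg$anchor_means
  for (v in c("weekday_bedtime", "weekday_risetime",
              "weekend_bedtime", "weekend_risetime")) {
    expect_equal(summ[[v]], anchors[[v]], tolerance = 1e-9)
  }
  # chronotype and method structure are present but group-centred, so they
  # contribute nothing to the means even at zero noise
  expect_true(any(coh$chronotype %in% c("M", "E")))
  expect_true(all(c("survey", "actigraphy") %in% coh$method))
})

test_that("chronotyped samples are separated by twice the offset", {
  cfg <- synth_config(noise_sd = 0, seed = 9, fraction_me_typed = 0.5)
  coh <- bin_samples(generate_cohort(cfg))
  g <- coh[coh$group_label == "12+", ]
  m <- g[g$chronotype == "M", ]; e <- g[g$chronotype == "E", ]
  expect_gt(nrow(m), 0); expect_gt(nrow(e), 0)
  expect_equal(mean(e$weekday_bedtime) - mean(m$weekday_bedtime), 2,
               tolerance = 0.2)
})

test_that("replicate cohort means concentrate as the CLT predicts", {
  # per-group mean of the weekend bedtime should fall within 3 sd/sqrt(n)
  # of its anchor in ~99.7% of replicate cohorts
  cfg <- synth_config(seed = 0)
  sizes <- cfg$group_sizes
  anchors <- cfg$anchor_means$weekend_bedtime
  n_rep <- 200
  hit <- matrix(FALSE, n_rep, length(sizes))
  for (r in seq_len(n_rep)) {
    coh <- bin_samples(generate_cohort(synth_config(seed = 1000 + r)))
    means <- tapply(coh$weekend_bedtime, coh$group_label, mean)
    hit[r, ] <- abs(as.numeric(means) - anchors) <= 3 * cfg$noise_sd / sqrt(sizes)
  }
  expect_gte(mean(hit), 0.97)
})

test_that("the method pair shares latent times and differs by the bias", {
  pair <- generate_method_pair(synth_config(seed = 2), n_samples = 200)
  expect_identical(pair$survey$weekday_bedtime, pair$actigraphy$weekday_bedtime)
  diff <- pair$survey$weekend_risetime - pair$actigraphy$weekend_risetime
  expect_equal(mean(diff), 0.9, tolerance = 1e-12)
  zero <- generate_method_pair(synth_config(seed = 2,
                                            survey_weekend_risetime_bias = 0),
                               n_samples = 20)
  expect_equal(zero$survey$weekend_risetime, zero$actigraphy$weekend_risetime)
})

test_that("the survey bias inflates the weekend-risetime discrepancy", {
  pair <- generate_method_pair(synth_config(seed = 3), n_samples = 100)
  sim <- simulate_age_group("16+")
  disc_of <- function(set) {
    g <- summarize_group(set)
    g$group_label <- "16+"
    d <- discrepancy_table(g, sim)
    d$discrepancy[d$quantity == "risetime_weekend"]
  }
  expect_gt(disc_of(pair$survey), disc_of(pair$actigraphy))
  expect_equal(disc_of(pair$survey) - disc_of(pair$actigraphy), 0.9,
               tolerance = 1e-9)
})
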