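# shared builders for the model tests

cp_zero <- function() circadian_params(amplitude = 0)
cp_default <- function() circadian_params()

# random valid homeostatic parameter set; wake/sleep durations are drawn
# first and converted to time constants through the zero-amplitude closed
# forms, so the relay has a sensible intrinsic period
random_params <- function(wake_range = c(13, 17), sleep_jitter = 1.5) {
  Xl <- runif(1, 0.4, 0.9)
  Xb <- Xl + runif(1, 0.03, 0.12)
  Xd <- Xb + runif(1, 1.5, 2.5)
  Xu <- Xd + runif(1, 1.5, 3.0)
  wake <- runif(1, wake_range[1], wake_range[2])
  sleep <- 24 - wake + runif(1, -sleep_jitter, sleep_jitter)
  Tb <- wake / log((Xu - Xb) / (Xu - Xd))
  Td <- sleep / log((Xd - Xl) / (Xb - Xl))
  homeostat_params(lower_asymptote = Xl, wake_threshold = Xb,
                   sleep_threshold = Xd, upper_asymptote = Xu,
                   decay_constant = Td, buildup_constant = Tb)
}

# zero-amplitude closed forms (the independent oracle for the event solver)
closed_form_buildup_time <- function(start_level, hp) {
  hp$buildup_constant *
    log((hp$upper_asymptote - start_level) /
          (hp$upper_asymptote - hp$sleep_threshold))
}
closed_form_decay_time <- function(start_level, hp) {
  hp$decay_constant *
    log((start_level - hp$lower_asymptote) /
          (hp$wake_threshold - hp$lower_asymptote))
}

default_schedule_sim <- function(label, weeks = 2) {
  g <- age_group_params(label)
  simulate_schedule(g$circadian, g$homeostat,
                    schedule = schedule_spec(g$free_risetime, g$weekday_alarm,
                                             weeks = weeks))
}
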