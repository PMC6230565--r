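#' Weekly schedule specification
#'
#' Describes the day-type protocol driven through the model: each entry of
#' `day_sequence` is the type of one *morning* (`"free"`: the wake switch is
#' model-determined; `"forced"`: the sleeper is woken by the alarm at
#' `weekday_alarm`).  The default protocol is two vacation mornings followed
#' by `weeks` school weeks of five forced mornings (Monday-Friday) and a
#' free weekend (Saturday, Sunday); the last week of such a protocol is the
#' steady week that [summarize_week()] reports.
#'
#' @param free_risetime_init Clock hour of the initial (vacation) wake that
#'   starts the simulation.
#' @param weekday_alarm Forced risetime on school mornings, clock hours.
#' @param day_sequence Character vector of `"free"`/`"forced"` morning
#'   types, or `NULL` to build the default protocol.
#' @param weeks Number of school weeks in the default protocol.
#' @return An object of class `schedule_spec`.
#' @examples
#' g <- age_group_params("12+")
#' schedule_spec(g$free_risetime, g$weekday_alarm)
#' @export
schedule_spec <- function(free_risetime_init, weekday_alarm,
                          day_sequence = NULL, weeks = 2) {
  if (is.null(day_sequence))
    day_sequence <- c("free", "free",
                      rep(c(rep("forced", 5), "free", "free"), weeks))
  day_sequence <- match.arg(day_sequence, c("free", "forced"),
                            several.ok = TRUE)
  if (length(day_sequence) < 1L) stop("day_sequence must be non-empty")
  stopifnot(is.numeric(free_risetime_init), is.numeric(weekday_alarm))
  structure(list(free_risetime_init = free_risetime_init,
                 weekday_alarm = weekday_alarm,
                 day_sequence = day_sequence),
            class = "schedule_spec")
}

#' @export
print.schedule_spec <- function(x, ...) {
  n_f <- sum(x$day_sequence == "forced")
  cat(sprintf(
    "Schedule: %d mornings (%d forced at %.2f, %d free), initial free wake %.2f\n",
    length(x$day_sequence), n_f, x$weekday_alarm,
    length(x$day_sequence) - n_f, x$free_risetime_init))
  invisible(x)
}

#' Simulate a sleep-wake schedule
#'
#' Drives the model through the day protocol of a [schedule_spec].  Every
#' bedtime is a model switch event (buildup crossing the sleep-onset set
#' point).  On a free morning the wake is the decay's threshold switch; on a
#' forced morning the decay is truncated at the alarm and the level it has
#' reached there is carried into the next buildup, which is the mechanism
#' that moves school-night bedtimes earlier than the free-running bedtime.
#'
#' The simulation runs on an absolute hour axis with day `d` spanning
#' `[24(d-1), 24d)`; the initial wake happens on day 1.
#'
#' @inheritParams switch_threshold
#' @param schedule A [schedule_spec].
#' @param solver_opts Passed to [next_switch_time()].
#' @return An object of class `sleep_schedule`: list with
#'   \describe{
#'     \item{days}{data.frame of sleep episodes, one per morning from the
#'       second onward: `day_index` (morning's day number), `day_type`,
#'       `bedtime` (previous evening's onset, clock hours, > 24 after
#'       midnight), `risetime` (clock hours), `time_in_bed` (h),
#'       `swa_at_bed`, `swa_at_rise` (relative SWA).}
#'     \item{segments}{data.frame of phase segments on the absolute axis:
#'       `phase`, `start_time`, `end_time`, `start_level`, `end_level`.}
#'     \item{spec, cp, hp, rule}{the inputs.}
#'   }
#' @examples
#' g <- age_group_params("12+")
#' sim <- simulate_schedule(g$circadian, g$homeostat,
#'                          schedule = schedule_spec(g$free_risetime, g$weekday_alarm))
#' head(sim$days)
#' @export
simulate_schedule <- function(cp, hp, rule = switch_rule(), schedule,
                              solver_opts = list()) {
  stopifnot(inherits(schedule, "schedule_spec"))
  types <- schedule$day_sequence
  n_days <- length(types)
  t_wake <- schedule$free_risetime_init            # day 1, absolute axis
  lvl <- free_start_level("buildup", t_wake, cp, hp, rule)
  seg <- vector("list", 2L * (n_days - 1L))
  rows <- vector("list", n_days - 1L)
  for (d in seq_len(n_days - 1L)) {
    t_bed <- next_switch_time("buildup", t_wake, lvl, cp, hp, rule, solver_opts)
    lvl_bed <- if (rule$carry_over_start)
      switch_threshold("buildup", t_bed, cp, hp, rule) else hp$sleep_threshold
    seg[[2L * d - 1L]] <- data.frame(
      phase = "buildup", start_time = t_wake, end_time = t_bed,
      start_level = lvl, end_level = lvl_bed)
    type_next <- types[d + 1L]
    if (type_next == "forced") {
      # first alarm instant strictly after bedtime
      t_rise <- t_bed + (schedule$weekday_alarm - t_bed) %% 24
      if (t_rise <= t_bed) t_rise <- t_rise + 24
      lvl_rise <- decay_level(t_rise, t_bed, lvl_bed, cp, hp)
      lvl <- if (rule$carry_over_start) lvl_rise else hp$wake_threshold
    } else {
      t_rise <- next_switch_time("decay", t_bed, lvl_bed, cp, hp, rule, solver_opts)
      lvl_rise <- switch_threshold("decay", t_rise, cp, hp, rule)
      lvl <- free_start_level("buildup", t_rise, cp, hp, rule)
    }
    seg[[2L * d]] <- data.frame(
      phase = "decay", start_time = t_bed, end_time = t_rise,
      start_level = lvl_bed, end_level = lvl_rise)
    rows[[d]] <- data.frame(
      day_index = d + 1L, day_type = type_next,
      bedtime = bed_clock_hour(t_bed), risetime = clock_hour(t_rise),
      time_in_bed = t_rise - t_bed,
      swa_at_bed = lvl_bed, swa_at_rise = lvl_rise)
    t_wake <- t_rise
  }
  structure(list(days = do.call(rbind, rows),
                 segments = do.call(rbind, seg),
                 spec = schedule, cp = cp, hp = hp, rule = rule),
            class = "sleep_schedule")
}

#' @export
print.sleep_schedule <- function(x, ...) {
  cat(sprintf("Simulated schedule: %d sleep episodes (%d after forced mornings)\n",
              nrow(x$days), sum(x$days$day_type == "forced")))
  print(utils::tail(x$days, 7), row.names = FALSE)
  invisible(x)
}

# Episodes of the last steady week: the trailing 5 forced + 2 free mornings.
steady_week_episodes <- function(days) {
  n <- nrow(days)
  if (n < 7L) stop("schedule too short: need at least one full week plus burn-in")
  idx <- (n - 6L):n
  wk <- days[idx, ]
  if (!identical(wk$day_type, c(rep("forced", 5), "free", "free")))
    stop("last seven mornings are not a 5-forced + 2-free school week")
  wk
}

#' Summarise the steady week
#'
#' Extracts weekday/weekend sleep times and the weekday-weekend shift
#' metrics (social jet lag) from the last full school week of a simulated
#' schedule.  In that week the seven episodes end on Monday..Sunday
#' mornings, so their onsets are the Sunday..Saturday nights.
#'
#' Reporting conventions (configurable through `aggregation`):
#' \describe{
#'   \item{`weekday_nights`}{`"mon_fri"` (default): average the onsets of
#'     the Monday-Friday calendar nights, i.e. the four school nights ending
#'     in an alarm plus the free Friday night.  `"school"`: the five nights
#'     preceding forced mornings (Sunday-Thursday).}
#'   \item{`weekend_bedtime`}{`"saturday"` (default): the Saturday-night
#'     onset.  `"fri_sat"`: mean of Friday and Saturday nights.}
#'   \item{`weekend_risetime`}{`"sat_sun"` (default): mean of the Saturday
#'     and Sunday free wake events.  `"sunday"`: Sunday only.}
#' }
#' The defaults are the conventions under which the packaged age-group
#' simulations reproduce the published discrepancy table.
#'
#' Times in bed are derived from the aggregated times by modular
#' subtraction; shifts are weekday minus weekend.
#'
#' @param sim A `sleep_schedule` from [simulate_schedule()] (or its `days`
#'   data.frame).
#' @param aggregation Optional list overriding the conventions above.
#' @return A one-row data.frame of class `week_summary` with columns
#'   `weekday_bedtime`, `weekday_risetime`, `weekend_bedtime`,
#'   `weekend_risetime`, `weekday_tib`, `weekend_tib`, `shift_bedtime`,
#'   `shift_risetime`, `shift_tib` (clock hours / hours).
#' @export
summarize_week <- function(sim, aggregation = list()) {
  agg <- utils::modifyList(list(weekday_nights = "mon_fri",
                                weekend_bedtime = "saturday",
                                weekend_risetime = "sat_sun"), aggregation)
  days <- if (inherits(sim, "sleep_schedule")) sim$days else sim
  wk <- steady_week_episodes(days)
  # rows 1..5: wake Mon..Fri (nights Sun..Thu); rows 6,7: wake Sat, Sun
  beds <- wk$bedtime; rises <- wk$risetime
  wd_bed <- switch(agg$weekday_nights,
                   mon_fri = mean(beds[2:6]),
                   school  = mean(beds[1:5]),
                   stop("unknown weekday_nights convention"))
  wd_rise <- mean(rises[1:5])
  we_bed <- switch(agg$weekend_bedtime,
                   saturday = beds[7],
                   fri_sat  = mean(beds[6:7]),
                   stop("unknown weekend_bedtime convention"))
  we_rise <- switch(agg$weekend_risetime,
                    sat_sun = mean(rises[6:7]),
                    sunday  = rises[7],
                    stop("unknown weekend_risetime convention"))
  out <- data.frame(
    weekday_bedtime = wd_bed, weekday_risetime = wd_rise,
    weekend_bedtime = we_bed, weekend_risetime = we_rise,
    weekday_tib = (wd_rise - wd_bed) %% 24,
    weekend_tib = (we_rise - we_bed) %% 24,
    shift_bedtime = wd_bed - we_bed,
    shift_risetime = wd_rise - we_rise)
  out$shift_tib <- out$weekday_tib - out$weekend_tib
  class(out) <- c("week_summary", "data.frame")
  out
}

#' SWA level at the alarm instant, day by day
#'
#' Evaluates the model state at the weekday alarm clock time on every day of
#' a simulated schedule, regardless of whether the sleeper is asleep
#' (decaying) or already awake (building up) at that instant.  On a steady
#' school week the profile is nearly flat: right before the alarm the SWA
#' level is almost the same from Monday to Sunday, which is why sleep debt
#' does not accumulate across the week in this model.
#'
#' @param sim A `sleep_schedule`.
#' @param alarm Clock hour at which to probe the state; defaults to the
#'   schedule's weekday alarm.
#' @return data.frame with `day_index`, `time` (absolute h), `phase`,
#'   `swa_level`.
#' @export
swa_at_alarm_profile <- function(sim, alarm = NULL) {
  stopifnot(inherits(sim, "sleep_schedule"))
  if (is.null(alarm)) alarm <- sim$spec$weekday_alarm
  segs <- sim$segments
  t0 <- segs$start_time[1L]; t1 <- segs$end_time[nrow(segs)]
  probes <- seq(floor(t0 / 24) * 24 + alarm, t1, by = 24)
  probes <- probes[probes >= t0]
  out <- lapply(probes, function(tp) {
    i <- which(segs$start_time <= tp & tp <= segs$end_time)[1L]
    if (is.na(i)) return(NULL)
    lv <- phase_level(segs$phase[i], tp, segs$start_time[i],
                      segs$start_level[i], sim$cp, sim$hp)
    data.frame(day_index = floor(tp / 24) + 1L, time = tp,
               phase = segs$phase[i], swa_level = lv)
  })
  do.call(rbind, out)
}

#' Dense SWA trajectory of a simulated schedule
#'
#' Samples the piecewise trajectory on a regular grid, for plotting or CSV
#' export.
#'
#' @param sim A `sleep_schedule`.
#' @param dt Sampling step, hours.
#' @return data.frame with `time_h` (absolute), `clock_h`, `swa_level`,
#'   `phase`, `day_index`.
#' @export
swa_trajectory <- function(sim, dt = 0.05) {
  stopifnot(inherits(sim, "sleep_schedule"))
  segs <- sim$segments
  out <- lapply(seq_len(nrow(segs)), function(i) {
    tt <- seq(segs$start_time[i], segs$end_time[i], by = dt)
    if (tt[length(tt)] < segs$end_time[i]) tt <- c(tt, segs$end_time[i])
    data.frame(time_h = tt, clock_h = tt %% 24,
               swa_level = phase_level(segs$phase[i], tt, segs$start_time[i],
                                       segs$start_level[i], sim$cp, sim$hp),
               phase = segs$phase[i], day_index = floor(tt / 24) + 1L)
  })
  do.call(rbind, out)
}

#' Plot a simulated schedule
#'
#' Base-graphics view of the SWA trajectory with the circadian-modulated
#' switching thresholds overlaid.
#'
#' @param x A `sleep_schedule`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sleep_schedule <- function(x, ...) {
  tr <- swa_trajectory(x)
  graphics::plot(tr$time_h / 24, tr$swa_level, type = "l",
                 xlab = "time (days)", ylab = "relative SWA", ...)
  tt <- seq(min(tr$time_h), max(tr$time_h), by = 0.1)
  graphics::lines(tt / 24, switch_threshold("buildup", tt, x$cp, x$hp, x$rule),
                  lty = 3, col = "grey40")
  graphics::lines(tt / 24, switch_threshold("decay", tt, x$cp, x$hp, x$rule),
                  lty = 3, col = "grey40")
  invisible(x)
}
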