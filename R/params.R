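#' Circadian modulation parameters
#'
#' Parameters of the sinusoidal circadian term
#' \deqn{C(t) = A \sin(2\pi t/\tau + \varphi_0)}
#' that modulates every parameter of the homeostatic (slow-wave-activity)
#' process: asymptotes and switching thresholds are shifted by \eqn{C(t)},
#' and the phase time constants by \eqn{-k\,C(t)}.
#'
#' Time is measured in decimal clock hours with \eqn{t = 0} at midnight, so
#' `initial_phase` anchors the circadian cycle to clock time.  With the
#' default anchor (3.66 rad) the term peaks close to 16:00 and bottoms out
#' close to 04:00, i.e. the wake drive is maximal in the late afternoon.
#'
#' @param amplitude Circadian amplitude `A`, relative SWA units (>= 0).
#' @param initial_phase Phase anchor `phi0` at clock midnight, radians.
#' @param period Entrained circadian period `tau`, hours (> 0).
#' @param modulation_gain Gain `k` applied to `C(t)` inside the effective
#'   time constants (dimensionless, >= 0).
#' @return An object of class `circadian_params`.
#' @examples
#' cp <- circadian_params()
#' circadian_term(0, cp)
#' @export
circadian_params <- function(amplitude = 0.5, initial_phase = 3.66,
                             period = 24, modulation_gain = 2) {
  stopifnot(is.numeric(amplitude), is.numeric(initial_phase),
            is.numeric(period), is.numeric(modulation_gain))
  if (period <= 0) stop("circadian period must be positive")
  if (amplitude < 0) stop("circadian amplitude must be non-negative")
  if (modulation_gain < 0) stop("modulation gain must be non-negative")
  structure(list(amplitude = amplitude, initial_phase = initial_phase,
                 period = period, modulation_gain = modulation_gain),
            class = "circadian_params")
}

#' Homeostatic (SWA) process parameters
#'
#' Asymptotes, switching thresholds and time constants of the two-phase
#' homeostatic process.  The state `X(t)` is expressed in relative
#' slow-wave-activity (SWA) units: during wake it builds up from the wake
#' threshold toward the upper asymptote with time constant `buildup_constant`;
#' during sleep it decays from the sleep-onset threshold toward the lower
#' asymptote with time constant `decay_constant`.
#'
#' @param lower_asymptote `SWA_l`, relative SWA the decay relaxes toward.
#' @param wake_threshold `SWA_b`, the lowest level of the decay: crossing it
#'   (downward) ends sleep.
#' @param sleep_threshold `SWA_d`, the highest level of the buildup: crossing
#'   it (upward) initiates sleep.
#' @param upper_asymptote `SWA_u`, relative SWA the buildup relaxes toward.
#' @param decay_constant `T_d`, hours.
#' @param buildup_constant `T_b`, hours.  The mechanism of the
#'   adolescent sleep-phase delay: this is the one parameter that increases
#'   systematically with age.
#' @return An object of class `homeostat_params`.
#' @examples
#' homeostat_params()
#' @export
homeostat_params <- function(lower_asymptote = 0.70, wake_threshold = 0.755,
                             sleep_threshold = 2.75, upper_asymptote = 5.00,
                             decay_constant = 2.40, buildup_constant = 27.81) {
  hp <- list(lower_asymptote = lower_asymptote, wake_threshold = wake_threshold,
             sleep_threshold = sleep_threshold, upper_asymptote = upper_asymptote,
             decay_constant = decay_constant, buildup_constant = buildup_constant)
  if (!all(vapply(hp, is.numeric, logical(1))))
    stop("all homeostatic parameters must be numeric")
  if (!(lower_asymptote < wake_threshold &&
        wake_threshold < sleep_threshold &&
        sleep_threshold < upper_asymptote))
    stop("levels must be ordered SWA_l < SWA_b < SWA_d < SWA_u")
  if (decay_constant <= 0 || buildup_constant <= 0)
    stop("time constants must be positive")
  structure(hp, class = "homeostat_params")
}

#' Switching rule for the threshold events
#'
#' Controls two conventions the verbal model description leaves open:
#' whether the switching thresholds share the circadian modulation of the
#' other parameters (`threshold_modulated`), and whether the level at which
#' a phase ends is carried over as the start level of the next phase
#' (`carry_over_start`) or reset to the nominal threshold.
#'
#' The defaults (both `TRUE`) are selected by [select_switch_rule()], which
#' re-simulates the steady free-running cycle for every packaged age-group
#' parameter set and picks the variant with the smallest maximum deviation
#' from the reported vacation bed- and risetimes.  Carry-over is also what
#' makes the weekday mechanism work: an alarm truncates the decay above the
#' wake threshold, and the excess level shortens the next buildup, sending
#' the model to bed earlier on school nights.
#'
#' @param threshold_modulated If `TRUE`, switching occurs at `SWA_d + C(t)` /
#'   `SWA_b + C(t)`; if `FALSE`, at the fixed `SWA_d` / `SWA_b`.
#' @param carry_over_start If `TRUE`, a phase starts at the level the
#'   previous phase actually reached (threshold level at a free switch,
#'   truncated decay level at an alarm).
#' @return An object of class `switch_rule`.
#' @export
switch_rule <- function(threshold_modulated = TRUE, carry_over_start = TRUE) {
  stopifnot(is.logical(threshold_modulated), length(threshold_modulated) == 1L,
            is.logical(carry_over_start), length(carry_over_start) == 1L,
            !is.na(threshold_modulated), !is.na(carry_over_start))
  structure(list(threshold_modulated = threshold_modulated,
                 carry_over_start = carry_over_start),
            class = "switch_rule")
}

#' @export
print.circadian_params <- function(x, ...) {
  cat("Circadian modulation: A =", x$amplitude,
      "rel.SWA, phi0 =", x$initial_phase, "rad, tau =", x$period,
      "h, k =", x$modulation_gain, "\n")
  invisible(x)
}

#' @export
print.homeostat_params <- function(x, ...) {
  cat("Homeostatic process (relative SWA):\n")
  cat(sprintf("  levels  SWA_l %.3f < SWA_b %.3f < SWA_d %.3f < SWA_u %.3f\n",
              x$lower_asymptote, x$wake_threshold,
              x$sleep_threshold, x$upper_asymptote))
  cat(sprintf("  time constants  T_b %.2f h (buildup), T_d %.2f h (decay)\n",
              x$buildup_constant, x$decay_constant))
  invisible(x)
}

#' @export
print.switch_rule <- function(x, ...) {
  cat("Switch rule: thresholds",
      if (x$threshold_modulated) "circadian-modulated" else "fixed",
      "| start levels", if (x$carry_over_start) "carried over" else "reset",
      "\n")
  invisible(x)
}

param_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "parameter_sets.json",
                          package = "rhythmostat", mustWork = TRUE)
      cache <<- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    }
    cache
  }
})

params_from_keys <- function(p) {
  list(
    circadian = circadian_params(amplitude = p$A, initial_phase = p$phi0,
                                 period = p$tau, modulation_gain = p$k),
    homeostat = homeostat_params(lower_asymptote = p$SWA_l,
                                 wake_threshold = p$SWA_b,
                                 sleep_threshold = p$SWA_d,
                                 upper_asymptote = p$SWA_u,
                                 decay_constant = p$T_d,
                                 buildup_constant = p$T_b),
    free_bedtime = p$t2, free_risetime = p$t1,
    weekday_alarm = if (is.null(p$weekday_risetime)) NA_real_ else p$weekday_risetime
  )
}

#' Packaged baseline parameter sets
#'
#' Two complete single-column parameter sets ship with the package: an
#' `"adult_baseline"` set originally derived from adult sleep-deprivation and
#' nap SWA experiments, and a `"highschool_survey"` set tuned to a
#' high-school cohort whose sleep times were recorded by survey, diary and
#' actigraphy.  Per-age sets are returned by [age_group_params()].
#'
#' @param name `"adult_baseline"` or `"highschool_survey"`.
#' @return A list with components `circadian` ([circadian_params]),
#'   `homeostat` ([homeostat_params]), `free_bedtime`, `free_risetime`
#'   (vacation t2/t1, clock hours) and `weekday_alarm` (clock hours or `NA`).
#' @examples
#' model_presets("adult_baseline")$homeostat
#' @export
model_presets <- function(name = c("adult_baseline", "highschool_survey")) {
  name <- match.arg(name)
  params_from_keys(param_fixture()$presets[[name]])
}

#' Labels of the packaged age groups
#'
#' @return Character vector of the eight age-group labels, youngest first.
#' @export
age_group_labels <- function() {
  vapply(param_fixture()$age_groups, `[[`, character(1), "label")
}

#' Age-group parameter set
#'
#' Returns the packaged model parameters for one of the eight age groups,
#' including the vacation bed/rise times (`t2`, `t1`) and the weekday alarm
#' used as schedule inputs.  Only `SWA_b`, `SWA_d`, `SWA_u`, `T_d`, `T_b`
#' and the schedule inputs vary across groups; the circadian term is
#' age-invariant.
#'
#' @param label One of [age_group_labels()], e.g. `"12+"`.
#' @return An object of class `age_group_params`: the [model_presets()] list
#'   plus `label` and `n_samples` (number of literature samples in the bin).
#' @examples
#' age_group_params("18+")$homeostat$buildup_constant
#' @export
age_group_params <- function(label) {
  groups <- param_fixture()$age_groups
  labs <- vapply(groups, `[[`, character(1), "label")
  i <- match(label, labs)
  if (is.na(i))
    stop("unknown age group '", label, "'; see age_group_labels()")
  g <- groups[[i]]
  out <- params_from_keys(g$params)
  out$label <- g$label
  out$n_samples <- g$n
  class(out) <- "age_group_params"
  out
}

#' @export
print.age_group_params <- function(x, ...) {
  cat("Age group", x$label, sprintf("(n = %d literature samples)\n", x$n_samples))
  print(x$homeostat)
  cat(sprintf("  vacation bedtime %.2f, risetime %.2f, weekday alarm %.2f (clock h)\n",
              x$free_bedtime, x$free_risetime, x$weekday_alarm))
  invisible(x)
}

#' Reported group-averaged sleep times
#'
#' The empirical reference surface: group-averaged weekday/weekend bed- and
#' risetimes (decimal clock hours, weekend bedtimes past midnight expressed
#' as > 24) for the eight age bins of the literature cohort, with the number
#' of samples per bin.
#'
#' @return A data.frame with columns `group_label`, `n_samples`,
#'   `weekday_bedtime`, `weekday_risetime`, `weekend_bedtime`,
#'   `weekend_risetime`.
#' @examples
#' empirical_sleep_times()
#' @export
empirical_sleep_times <- function() {
  groups <- param_fixture()$age_groups
  do.call(rbind, lapply(groups, function(g) {
    data.frame(group_label = g$label, n_samples = g$n,
               weekday_bedtime = g$empirical$weekday_bedtime,
               weekday_risetime = g$empirical$weekday_risetime,
               weekend_bedtime = g$empirical$weekend_bedtime,
               weekend_risetime = g$empirical$weekend_risetime,
               stringsAsFactors = FALSE)
  }))
}

#' Published discrepancy reference values
#'
#' The published empirical-minus-simulated discrepancy table for the eight
#' age groups, used by the test suite as a reproduction target.
#'
#' @return A data.frame: one row per quantity, one column per group label.
#' @keywords internal
#' @export
reference_discrepancies <- function() {
  ref <- param_fixture()$reference_discrepancies
  out <- as.data.frame(lapply(ref$values, unlist), check.names = FALSE)
  out <- as.data.frame(t(out))
  colnames(out) <- unlist(ref$groups)
  out$quantity <- unlist(ref$quantities)
  rownames(out) <- NULL
  out[, c("quantity", unlist(ref$groups))]
}
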