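#' Circadian term C(t)
#'
#' Evaluates \eqn{C(t) = A \sin(2\pi t/\tau + \varphi_0)} at clock time `t`
#' (hours; values outside \[0, 24) wrap naturally through the sine).
#'
#' @param t Time, decimal clock hours (vectorised).
#' @param cp A [circadian_params] object.
#' @return Relative-SWA offset in `[-A, A]`.
#' @export
circadian_term <- function(t, cp) {
  cp$amplitude * sin(2 * pi * t / cp$period + cp$initial_phase)
}

# Effective time constant of a phase at time t; signals an error if the
# circadian modulation drives it non-positive (invalid parameterisation).
effective_tc <- function(phase, t, cp, hp) {
  base <- if (phase == "buildup") hp$buildup_constant else hp$decay_constant
  tc <- base - cp$modulation_gain * circadian_term(t, cp)
  if (any(tc <= 0))
    stop("non-positive effective time constant in ", phase,
         " phase: T - k*C(t) must stay positive", call. = FALSE)
  tc
}

#' SWA level during the wake (buildup) phase
#'
#' \deqn{X(t) = [X_u + C(t)] - \{[X_u + C(t)] - X_0\}\, e^{-(t-t_1)/[T_b - kC(t)]}}
#' where \eqn{X_0} is the level at which the phase starts (the wake threshold
#' after an undisturbed sleep, or a truncated decay level after an alarm).
#' At `t = start_time` the start level is returned exactly.
#'
#' @param t Evaluation time(s), clock hours, `>= start_time`.
#' @param start_time Phase onset (risetime), clock hours.
#' @param start_level SWA level at onset, relative SWA.
#' @param cp,hp [circadian_params] / [homeostat_params].
#' @return Relative SWA level(s).
#' @export
buildup_level <- function(t, start_time, start_level, cp, hp) {
  if (any(t < start_time)) stop("t must be >= start_time")
  co <- circadian_term(t, cp)
  asym <- hp$upper_asymptote + co
  out <- asym - (asym - start_level) *
    exp(-(t - start_time) / effective_tc("buildup", t, cp, hp))
  out[t == start_time] <- start_level    # boundary condition, exactly
  out
}

#' SWA level during the sleep (decay) phase
#'
#' \deqn{X(t) = [X_l + C(t)] + \{X_0 - [X_l + C(t)]\}\, e^{-(t-t_2)/[T_d - kC(t)]}}
#' with start level \eqn{X_0} (the sleep-onset threshold level under the
#' default carry-over rule).  At `t = start_time` the start level is
#' returned exactly; with zero amplitude the level decays monotonically
#' toward the lower asymptote.
#'
#' @inheritParams buildup_level
#' @param start_time Phase onset (bedtime), clock hours.
#' @return Relative SWA level(s).
#' @export
decay_level <- function(t, start_time, start_level, cp, hp) {
  if (any(t < start_time)) stop("t must be >= start_time")
  co <- circadian_term(t, cp)
  asym <- hp$lower_asymptote + co
  out <- asym + (start_level - asym) *
    exp(-(t - start_time) / effective_tc("decay", t, cp, hp))
  out[t == start_time] <- start_level    # boundary condition, exactly
  out
}

phase_level <- function(phase, t, start_time, start_level, cp, hp) {
  if (phase == "buildup") buildup_level(t, start_time, start_level, cp, hp)
  else decay_level(t, start_time, start_level, cp, hp)
}

#' Switching threshold (set point) of a phase
#'
#' The buildup phase ends when the level reaches the sleep-onset set point
#' (`SWA_d`), the decay phase when it falls to the wake set point (`SWA_b`).
#' Under the default rule both set points share the circadian modulation,
#' i.e. the thresholds are `SWA_d + C(t)` and `SWA_b + C(t)`.
#'
#' @param phase `"buildup"` or `"decay"`.
#' @param t Time(s), clock hours.
#' @param cp,hp,rule Model parameter objects ([switch_rule] for `rule`).
#' @return Threshold level(s), relative SWA.
#' @export
switch_threshold <- function(phase, t, cp, hp, rule = switch_rule()) {
  phase <- match.arg(phase, c("buildup", "decay"))
  base <- if (phase == "buildup") hp$sleep_threshold else hp$wake_threshold
  if (rule$threshold_modulated) base + circadian_term(t, cp) else base + 0 * t
}

#' Locate the next phase switch
#'
#' Finds the smallest `t > start_time` at which the phase level crosses its
#' switching threshold: the buildup crossing upward through the sleep-onset
#' set point, the decay crossing downward through the wake set point.  The
#' crossing is bracketed by scanning a regular grid and then refined by
#' bisection; tangential touches that do not change sign are ignored.
#'
#' @inheritParams switch_threshold
#' @param start_time Phase onset, clock hours.
#' @param start_level Level at onset; must lie strictly on the pre-switch
#'   side of the threshold (below it for buildup, above it for decay).
#' @param solver_opts List: `grid_step` (h, default 0.01), `horizon` (h,
#'   default 48; no crossing within the horizon is an error of class
#'   `rhythmostat_no_switch`) and `tol` (bisection width, h, default 1e-10).
#' @return Switch time, clock hours (same axis as `start_time`).
#' @examples
#' cp <- circadian_params(amplitude = 0)          # pure exponential relay
#' hp <- homeostat_params()
#' t_bed <- next_switch_time("buildup", 9.64, hp$wake_threshold, cp, hp)
#' # equals the closed-form t1 + Tb*log((Xu - Xb)/(Xu - Xd)):
#' 9.64 + hp$buildup_constant * log((5 - 0.755) / (5 - 2.75))
#' @export
next_switch_time <- function(phase, start_time, start_level, cp, hp,
                             rule = switch_rule(), solver_opts = list()) {
  phase <- match.arg(phase, c("buildup", "decay"))
  opts <- utils::modifyList(list(grid_step = 0.01, horizon = 48, tol = 1e-10),
                            solver_opts)
  sgn <- if (phase == "buildup") 1 else -1
  gap <- function(t) sgn * (switch_threshold(phase, t, cp, hp, rule) -
                              phase_level(phase, t, start_time, start_level, cp, hp))
  g0 <- gap(start_time)
  if (g0 <= 0)
    stop("start_level is not strictly on the pre-switch side of the threshold",
         call. = FALSE)
  grid <- seq(start_time, start_time + opts$horizon, by = opts$grid_step)
  gv <- gap(grid)
  idx <- which(gv[-length(gv)] > 0 & gv[-1] <= 0)
  if (length(idx) == 0L)
    stop(structure(class = c("rhythmostat_no_switch", "error", "condition"),
                   list(message = sprintf(
                     "no %s switch within %.1f h horizon (non-switching trajectory)",
                     phase, opts$horizon), call = sys.call())))
  lo <- grid[idx[1L]]; hi <- grid[idx[1L] + 1L]
  while (hi - lo > opts$tol) {
    mid <- (lo + hi) / 2
    if (gap(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Start level of a phase that begins at a free (threshold) switch at time t.
# Under carry-over the new phase starts where the old one ended, i.e. at the
# threshold level of the *previous* phase at the switch time; with reset it
# starts at the nominal fixed threshold.
free_start_level <- function(new_phase, t, cp, hp, rule) {
  prev <- if (new_phase == "buildup") "decay" else "buildup"
  if (rule$carry_over_start) switch_threshold(prev, t, cp, hp, rule)
  else if (new_phase == "buildup") hp$wake_threshold else hp$sleep_threshold
}

# Map an absolute hour to a reporting clock hour: risetimes in [0, 24),
# bedtimes in (12, 36] so that post-midnight onsets read as > 24.
clock_hour <- function(t) t %% 24
bed_clock_hour <- function(t) { x <- t %% 24; ifelse(x < 12, x + 24, x) }

#' Steady free-running sleep-wake cycle
#'
#' Iterates alternating buildup/decay threshold switches with no alarm until
#' successive cycles repeat, i.e. the relay oscillator has entrained to the
#' circadian period.  The converged cycle's sleep onset is reported as the
#' free (vacation) bedtime and its wake switch as the free risetime.
#'
#' @inheritParams switch_threshold
#' @param init_risetime Clock hour at which the first wake phase starts.
#' @param max_cycles Iteration cap; exceeding it returns a partial result
#'   flagged `converged = FALSE` (with zero circadian amplitude the relay
#'   has its own intrinsic period and never phase-locks to the clock).
#' @param tol Convergence tolerance, hours: successive bed- and risetimes
#'   must each move less than `tol`.
#' @param solver_opts Passed to [next_switch_time()].
#' @return An object of class `free_run_cycle`: list with `bedtime`,
#'   `risetime` (clock hours, bedtime > 24 when past midnight),
#'   `wake_duration`, `sleep_duration`, `period` (hours), `converged`,
#'   `n_iterations`.
#' @examples
#' g <- age_group_params("12+")
#' simulate_free_run(g$circadian, g$homeostat, init_risetime = g$free_risetime)
#' @export
simulate_free_run <- function(cp, hp, rule = switch_rule(), init_risetime = 8,
                              max_cycles = 50, tol = 1e-4, solver_opts = list()) {
  stopifnot(tol > 0)
  t <- init_risetime
  lvl <- free_start_level("buildup", t, cp, hp, rule)
  prev_bed <- prev_rise <- NA_real_
  converged <- FALSE
  bed <- rise <- NA_real_
  period <- NA_real_
  it <- 0L
  for (i in seq_len(max_cycles)) {
    it <- i
    t_bed <- next_switch_time("buildup", t, lvl, cp, hp, rule, solver_opts)
    lvl_bed <- if (rule$carry_over_start)
      switch_threshold("buildup", t_bed, cp, hp, rule) else hp$sleep_threshold
    t_rise <- next_switch_time("decay", t_bed, lvl_bed, cp, hp, rule, solver_opts)
    lvl <- free_start_level("buildup", t_rise, cp, hp, rule)
    bed <- bed_clock_hour(t_bed)
    rise <- clock_hour(t_rise)
    period <- t_rise - t
    if (!is.na(prev_bed) &&
        abs(bed - prev_bed) < tol && abs(rise - prev_rise) < tol) {
      converged <- TRUE
      break
    }
    prev_bed <- bed; prev_rise <- rise
    t <- t_rise
  }
  structure(list(bedtime = bed, risetime = rise,
                 wake_duration = period - (t_rise - t_bed),
                 sleep_duration = t_rise - t_bed,
                 period = period, converged = converged, n_iterations = it),
            class = "free_run_cycle")
}

#' @export
print.free_run_cycle <- function(x, ...) {
  cat(sprintf(
    "Free-running cycle: bedtime %.2f, risetime %.2f (clock h); wake %.2f h, sleep %.2f h, period %.3f h\n",
    x$bedtime, x$risetime, x$wake_duration, x$sleep_duration, x$period))
  cat(if (x$converged) sprintf("converged in %d cycles\n", x$n_iterations)
      else sprintf("NOT converged after %d cycles\n", x$n_iterations))
  invisible(x)
}

#' Calibrate the buildup time constant from free-day sleep times
#'
#' Inverse problem: given the free (vacation) risetime and bedtime, find the
#' buildup time constant `T_b` for which the wake phase started at the
#' risetime (at the wake set-point level) reaches the sleep-onset set point
#' exactly at the bedtime.  This is how per-age `T_b` values are obtained
#' from reported vacation sleep times.  The crossing time is strictly
#' increasing in `T_b`, so the root is bracketed by expansion and refined by
#' bisection.
#'
#' With zero circadian amplitude the closed form
#' \deqn{T_b = (t_2 - t_1) / \log[(X_u - X_b)/(X_u - X_d)]}
#' is recovered exactly.
#'
#' @param target_bedtime,target_risetime Free-day t2 and t1, clock hours
#'   (bedtime may be > 24; a bedtime numerically before the risetime is
#'   interpreted as the following night).
#' @param cp,rule See [switch_threshold()].
#' @param hp [homeostat_params]; its `buildup_constant` is ignored and
#'   re-estimated.
#' @param tol Bisection tolerance on `T_b`, hours.
#' @return Calibrated `T_b`, hours.
#' @examples
#' g <- age_group_params("18+")
#' calibrate_buildup_constant(25.40, 9.64, g$circadian, g$homeostat)
#' @export
calibrate_buildup_constant <- function(target_bedtime, target_risetime,
                                       cp, hp, rule = switch_rule(),
                                       tol = 1e-6) {
  t1 <- target_risetime
  t2 <- target_bedtime
  if (t2 <= t1) t2 <- t2 + 24
  wake <- t2 - t1
  if (wake <= 0 || wake >= 24) stop("target wake duration must lie in (0, 24) h")
  start_lvl <- free_start_level("buildup", t1, cp, hp, rule)
  bed_for <- function(Tb) {
    hp2 <- hp; hp2$buildup_constant <- Tb
    next_switch_time("buildup", t1, start_lvl, cp, hp2, rule,
                     solver_opts = list(horizon = 30))
  }
  # the effective constant Tb - k*C must stay positive
  lo <- cp$modulation_gain * cp$amplitude + 0.1
  hi <- max(2 * wake, lo + 1)
  f_lo <- tryCatch(bed_for(lo) - t2, rhythmostat_no_switch = function(e) Inf)
  if (f_lo > 0) stop("target bedtime unreachable: too early for any valid T_b")
  f_hi <- tryCatch(bed_for(hi) - t2, rhythmostat_no_switch = function(e) Inf)
  n_expand <- 0L
  while (f_hi < 0 && n_expand < 20L) {
    hi <- hi * 2
    f_hi <- tryCatch(bed_for(hi) - t2, rhythmostat_no_switch = function(e) Inf)
    n_expand <- n_expand + 1L
  }
  if (f_hi < 0) stop("target bedtime unreachable: cannot bracket T_b")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- tryCatch(bed_for(mid) - t2, rhythmostat_no_switch = function(e) Inf)
    if (f_mid < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
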