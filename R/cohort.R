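#' Validate a sample-level sleep-times table
#'
#' Checks (and returns) a data.frame of literature samples, one row per
#' published sample: identifier, mean participant age, number of subjects,
#' acquisition method, chronotype label and the four sleep times in decimal
#' clock hours (bedtimes past midnight expressed as > 24).
#'
#' @param x data.frame with columns `sample_id`, `mean_age`, `n_subjects`,
#'   `method` (`survey`/`diary`/`actigraphy`), `chronotype` (`all`/`M`/`E`),
#'   `weekday_bedtime`, `weekday_risetime`, `weekend_bedtime`,
#'   `weekend_risetime`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
as_sample_records <- function(x) {
  needed <- c("sample_id", "mean_age", "n_subjects", "method", "chronotype",
              "weekday_bedtime", "weekday_risetime",
              "weekend_bedtime", "weekend_risetime")
  miss <- setdiff(needed, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(x)) {
    if (any(x$mean_age <= 0 | x$mean_age >= 30))
      stop("mean_age must lie in (0, 30) years")
    if (any(x$n_subjects < 1)) stop("n_subjects must be >= 1")
    tm <- as.matrix(x[, needed[6:9]])
    if (any(tm <= 0 | tm >= 30)) stop("sleep times must lie in (0, 30) clock hours")
    if (!all(x$method %in% c("survey", "diary", "actigraphy")))
      stop("method must be survey, diary or actigraphy")
    if (!all(x$chronotype %in% c("all", "M", "E")))
      stop("chronotype must be all, M or E")
  }
  invisible(x)
}

default_bin_edges <- c(6, 10, 12, 14, 15, 16, 18)

bin_labels_from_edges <- function(edges) {
  c(paste0("<=", edges[1]), paste0(edges[-length(edges)], "+"),
    paste0(edges[length(edges)], "+"))
}

#' Assign samples to age bins
#'
#' Bins are left-open/right-closed at the printed boundaries: the youngest
#' bin is `age <= edges[1]`, then `edges[i] < age <= edges[i+1]`, and the
#' oldest bin is open-ended (`age > last edge`).  With the default edges
#' this reproduces the eight groups `<=6, 6+, 10+, 12+, 14+, 15+, 16+, 18+`.
#'
#' @param samples A sample table (see [as_sample_records()]).
#' @param bin_edges Strictly increasing ages (years).
#' @return `samples` with a `group_label` factor column added (levels in
#'   age order).
#' @examples
#' coh <- generate_cohort(synth_config(seed = 1))
#' table(bin_samples(coh)$group_label)
#' @export
bin_samples <- function(samples, bin_edges = default_bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  as_sample_records(samples)
  labs <- bin_labels_from_edges(bin_edges)
  if (nrow(samples) == 0L) {
    samples$group_label <- factor(character(0), levels = labs)
    return(samples)
  }
  # left-open intervals: age equal to a printed boundary stays in the lower
  # bin (age 6 belongs to "<=6")
  idx <- findInterval(samples$mean_age, bin_edges, left.open = TRUE) + 1L
  bad <- samples$mean_age <= 0
  if (any(bad))
    stop("samples outside all bins: ",
         paste(samples$sample_id[bad], collapse = ", "))
  samples$group_label <- factor(labs[idx], levels = labs)
  samples
}

#' Aggregate one age group
#'
#' Group means of the four sleep times with two-sided 95\% Student-t
#' confidence intervals computed across samples.  Each literature sample
#' counts as one unit by default; `weighting = "n_subjects"` weights the
#' means (not the CIs) by sample size.  Times in bed are derived from the
#' aggregated times by modular subtraction.
#'
#' @param samples Sample table for one group.
#' @param weighting `"none"` (default) or `"n_subjects"`.
#' @return One-row data.frame: `n_samples`, then for each of the four times
#'   the mean and CI half-width (`*_ci`; `NA` with a warning when only one
#'   sample is present), plus `weekday_tib` and `weekend_tib`.
#' @export
summarize_group <- function(samples, weighting = c("none", "n_subjects")) {
  weighting <- match.arg(weighting)
  as_sample_records(samples)
  if (nrow(samples) < 1L) stop("summarize_group needs at least one sample")
  vars <- c("weekday_bedtime", "weekday_risetime",
            "weekend_bedtime", "weekend_risetime")
  w <- if (weighting == "n_subjects") samples$n_subjects else rep(1, nrow(samples))
  if (nrow(samples) == 1L)
    warning("single sample in group: CI undefined", call. = FALSE)
  out <- list(n_samples = nrow(samples))
  for (v in vars) {
    xs <- samples[[v]]
    m <- stats::weighted.mean(xs, w)
    ci <- if (length(xs) > 1L)
      stats::qt(0.975, df = length(xs) - 1L) * stats::sd(xs) / sqrt(length(xs))
    else NA_real_
    out[[v]] <- m
    out[[paste0(v, "_ci")]] <- ci
  }
  out$weekday_tib <- (out$weekday_risetime - out$weekday_bedtime) %% 24
  out$weekend_tib <- (out$weekend_risetime - out$weekend_bedtime) %% 24
  as.data.frame(out)
}

#' Aggregate a whole cohort into age-group summaries
#'
#' Convenience wrapper: bins the samples and applies [summarize_group()]
#' per bin, returning a table shaped like the published group-averaged
#' sleep-times rows.
#'
#' @inheritParams bin_samples
#' @inheritParams summarize_group
#' @return data.frame with one row per non-empty group, `group_label` first.
#' @export
summarize_cohort <- function(samples, bin_edges = default_bin_edges,
                             weighting = "none") {
  binned <- bin_samples(samples, bin_edges)
  parts <- lapply(split(binned, binned$group_label, drop = TRUE), function(g)
    cbind(group_label = as.character(g$group_label[1L]),
          summarize_group(g, weighting)))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Simulate one age group's school week
#'
#' Runs the packaged (or supplied) parameters of an age group through the
#' default vacation + school-week protocol and summarises the steady week.
#'
#' @param params An `age_group_params` object (or a group label).
#' @param weeks School weeks simulated after the two-day vacation burn-in.
#' @param aggregation Passed to [summarize_week()].
#' @return One-row data.frame: `group_label` plus the [summarize_week()]
#'   columns.
#' @examples
#' simulate_age_group("18+")
#' @export
simulate_age_group <- function(params, weeks = 2, aggregation = list()) {
  if (is.character(params)) params <- age_group_params(params)
  stopifnot(inherits(params, "age_group_params"))
  spec <- schedule_spec(params$free_risetime, params$weekday_alarm,
                        weeks = weeks)
  sim <- simulate_schedule(params$circadian, params$homeostat,
                           schedule = spec)
  cbind(group_label = params$label, summarize_week(sim, aggregation))
}

discrepancy_quantities <- c("bedtime_weekday", "bedtime_weekend",
                            "risetime_weekday", "risetime_weekend",
                            "tib_weekday", "tib_weekend",
                            "shift_bedtime", "shift_risetime", "shift_tib")

summary_to_quantities <- function(s) {
  c(bedtime_weekday = s$weekday_bedtime, bedtime_weekend = s$weekend_bedtime,
    risetime_weekday = s$weekday_risetime, risetime_weekend = s$weekend_risetime,
    tib_weekday = s$weekday_tib, tib_weekend = s$weekend_tib,
    shift_bedtime = s$weekday_bedtime - s$weekend_bedtime,
    shift_risetime = s$weekday_risetime - s$weekend_risetime,
    shift_tib = s$weekday_tib - s$weekend_tib)
}

#' Empirical-minus-simulated discrepancy table
#'
#' For each group present in both inputs, computes empirical minus simulated
#' values for the six sleep times (bedtime/risetime/time-in-bed on weekdays
#' and weekends) and the three weekday-minus-weekend shifts (the social-jet-
#' lag metrics); the shift rows are discrepancies of shifts, i.e. empirical
#' shift minus simulated shift.  The sign convention makes a positive
#' weekend-risetime discrepancy mean "reported wake later than simulated".
#'
#' @param empirical data.frame with `group_label`, the four sleep times and
#'   (optionally) `weekday_tib`/`weekend_tib`; TIBs are derived by modular
#'   subtraction when absent.  [summarize_cohort()] output fits directly.
#' @param simulated Same layout; [simulate_age_group()] rows fit directly.
#' @return Long data.frame of class `discrepancy_table`: `group_label`,
#'   `quantity`, `empirical`, `simulated`, `discrepancy` (hours, unrounded;
#'   use [format_discrepancies()] for the reporting layer).
#' @export
discrepancy_table <- function(empirical, simulated) {
  if (!setequal(empirical$group_label, simulated$group_label) ||
      anyDuplicated(empirical$group_label) || anyDuplicated(simulated$group_label))
    stop("empirical and simulated tables must cover the same group labels exactly")
  fill_tib <- function(d) {
    if (is.null(d$weekday_tib))
      d$weekday_tib <- (d$weekday_risetime - d$weekday_bedtime) %% 24
    if (is.null(d$weekend_tib))
      d$weekend_tib <- (d$weekend_risetime - d$weekend_bedtime) %% 24
    d
  }
  empirical <- fill_tib(empirical); simulated <- fill_tib(simulated)
  out <- lapply(empirical$group_label, function(g) {
    e <- summary_to_quantities(empirical[empirical$group_label == g, ])
    s <- summary_to_quantities(simulated[simulated$group_label == g, ])
    data.frame(group_label = g, quantity = discrepancy_quantities,
               empirical = as.numeric(e), simulated = as.numeric(s),
               discrepancy = as.numeric(e - s))
  })
  out <- do.call(rbind, out)
  class(out) <- c("discrepancy_table", "data.frame")
  out
}

#' Discrepancies in published wide layout
#'
#' Reporting layer: quantities as rows, groups as columns, rounded to
#' 0.01 h (rounding happens only here, never inside the solvers).
#'
#' @param disc A [discrepancy_table()] result.
#' @param digits Decimal places.
#' @return data.frame, first column `quantity`.
#' @export
format_discrepancies <- function(disc, digits = 2) {
  groups <- unique(disc$group_label)
  wide <- data.frame(quantity = discrepancy_quantities)
  for (g in groups)
    wide[[g]] <- round(disc$discrepancy[disc$group_label == g][
      match(discrepancy_quantities, disc$quantity[disc$group_label == g])], digits)
  wide
}

#' Mean weekday sleep loss across the cohort
#'
#' The sample-size-weighted mean, over age groups, of the weekend-minus-
#' weekday difference in time in bed: the average amount of sleep lost per
#' school night to the alarm.  Applied to the packaged group-averaged times
#' this exceeds one hour.
#'
#' @param summaries data.frame with `group_label`, the four sleep times (or
#'   `weekday_tib`/`weekend_tib` directly).
#' @param group_sizes Named numeric vector (names = group labels) or `NULL`
#'   to use an `n_samples` column.
#' @return Hours (scalar).
#' @examples
#' weekday_sleep_loss(empirical_sleep_times())
#' @export
weekday_sleep_loss <- function(summaries, group_sizes = NULL) {
  need <- age_group_labels()
  if (!all(need %in% summaries$group_label))
    stop("incomplete cohort: missing groups ",
         paste(setdiff(need, summaries$group_label), collapse = ", "))
  if (is.null(group_sizes)) {
    if (is.null(summaries$n_samples))
      stop("group_sizes not given and no n_samples column present")
    group_sizes <- stats::setNames(summaries$n_samples, summaries$group_label)
  }
  if (is.null(summaries$weekday_tib))
    summaries$weekday_tib <- (summaries$weekday_risetime - summaries$weekday_bedtime) %% 24
  if (is.null(summaries$weekend_tib))
    summaries$weekend_tib <- (summaries$weekend_risetime - summaries$weekend_bedtime) %% 24
  loss <- summaries$weekend_tib - summaries$weekday_tib
  stats::weighted.mean(loss, as.numeric(group_sizes[summaries$group_label]))
}
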