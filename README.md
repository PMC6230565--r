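# rhythmostat

Simulation of human sleep-wake timing with a circadian-modulated
two-process model, and of how the conflict between school alarms and the
biologically preferred sleep phase — *social jet lag* — develops from
childhood to early adulthood.

## The science

Homeostatic sleep pressure, indexed by relative slow-wave activity (SWA),
rises during wake and falls during sleep.  In this model both phases are
exponentials whose parameters are all modulated by a circadian sinusoid
`C(t) = A sin(2πt/τ + φ0)`:

* wake: `X(t) = [SWA_u + C(t)] − {[SWA_u + C(t)] − X0} e^{−(t−t1)/[T_b − kC(t)]}`
* sleep: `X(t) = [SWA_l + C(t)] + {X0 − [SWA_l + C(t)]} e^{−(t−t2)/[T_d − kC(t)]}`

Sleep starts when the buildup reaches the circadian-modulated set point
`SWA_d + C(t)`, wake starts when the decay falls to `SWA_b + C(t)` — or at
the weekday alarm, whichever comes first.  A truncated decay carries its
surplus level into the next buildup, so school-week sleep restriction
moves bedtimes *earlier* instead of accumulating a repayable sleep debt.

Across eight age groups (≤6 … 18+), reproducing the reported weekday and
weekend sleep times requires changing essentially **one** parameter: the
buildup (wake-phase) time constant `T_b`, which grows from 18.39 h in
young children to 27.81 h in young adults.  That single change lengthens
the preferred wake episode, delays bedtime and shortens sleep — the
adolescent sleep-phase delay.  The package simulates weekly schedules per
age group, aggregates sample-level sleep-time tables with 95% confidence
intervals, computes empirical-minus-simulated discrepancy tables and
social-jet-lag shift metrics, calibrates `T_b` from free-day sleep times,
and generates synthetic literature cohorts for fully self-contained runs.

## Worked example

```r
library(rhythmostat)

g <- age_group_params("16+")
g
#> Age group 16+ (n = 21 literature samples)
#> Homeostatic process (relative SWA):
#>   levels  SWA_l 0.700 < SWA_b 0.755 < SWA_d 2.750 < SWA_u 5.000
#>   time constants  T_b 26.14 h (buildup), T_d 2.55 h (decay)
#>   vacation bedtime 24.78, risetime 9.53, weekday alarm 6.70 (clock h)

simulate_free_run(g$circadian, g$homeostat, init_risetime = g$free_risetime)
#> Free-running cycle: bedtime 24.82, risetime 9.81 (clock h); wake 15.00 h, sleep 9.00 h, period 24.000 h
#> converged in 4 cycles

simulate_age_group("16+")
#>   group_label weekday_bedtime weekday_risetime weekend_bedtime weekend_risetime
#> 1         16+            23.4              6.7            24.8             9.54
#>   weekday_tib weekend_tib shift_bedtime shift_risetime shift_tib
#> 1        7.27        8.77         -1.34          -2.84      -1.5
```

The free-running (vacation) cycle entrains to the 24-h circadian period
with bedtime 00:49 and wake 09:49.  Forcing the 06:42 school alarm on it
pulls weekday bedtimes to 23:26 — an hour and twenty minutes of social
jet lag in bedtime, and 1.5 h of sleep lost per school night relative to
the weekend.  `reproduce_tables()` runs all eight age groups and prints
the full empirical-minus-simulated discrepancy table in hours, together
with the cohort-level weekday sleep loss (1.13 h per school night,
sample-size-weighted).

The command-line wrapper exposes the same analyses:

```sh
Rscript inst/cli/rhythmostat.R simulate --age-group 12+ --weeks 2
Rscript inst/cli/rhythmostat.R synth --seed 42 --out cohort.csv
Rscript inst/cli/rhythmostat.R cohort --in cohort.csv
Rscript inst/cli/rhythmostat.R reproduce --out-dir results
```

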