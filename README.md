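# gsreplay

Group sequential designs for two-arm randomized trials whose primary
outcome is a patient-reported outcome measure (PROM) collected repeatedly
during follow-up — and calendar-time *replay* of such designs on dated
trial records.

## Why

In pragmatic trials (surgery is the motivating field) the primary outcome
is often measured a year or more after randomization, so by the time
enough primary outcomes exist to justify stopping, recruitment has already
finished. But the same PROM is usually collected earlier — at 3, 6, 9
months — and within-participant correlations between occasions are strong
(0.5–0.9). A longitudinal multivariate-normal model that uses *all*
outcome data therefore accrues statistical information about the
primary-time treatment effect much faster than the primary outcome alone,
opening a genuine *window of opportunity* for interim futility/efficacy
stopping.

The core quantities: with $Y_i \sim \mathrm{MVN}(\mu_{a(i)}, \Sigma)$ over
the modelled occasions (saturated per-arm means, one unstructured
$\Sigma$, missing-at-random likelihood), the treatment effect at the
primary time $t$ is $\beta_t$, its standardized statistic
$Z = \beta_t/\mathrm{sd}(\beta_t)$, and the information
$I = 1/\mathrm{var}(\beta_t)$. Interim analyses trigger when observed $I$
reaches planned levels $I^*_k$; stopping is decided against error-spending
boundaries $(l_k, u_k)$ solved under the canonical joint law
$\mathrm{cov}(Z_j, Z_k) = \sqrt{I_j/I_k}$. A primary-only comparison
analysis ($\beta 0_t$, $Z0$, $I0$, all correlations forced to zero) is
carried alongside throughout.

## What's in the package

| area | functions |
|---|---|
| longitudinal model | `fit_mvn_longitudinal()`, `fit_primary_only()`, `estimate_with_fixed_cov()` |
| spending boundaries | `make_spending_plan()`, `compute_boundaries()`, `exit_probabilities()` |
| information planning | `planned_accrual()`, `expected_information()`, `information_fractions()` |
| trial replay | `window_of_opportunity()`, `snapshot()`, `replay()`, `overrun_analysis()` |
| synthetic trials | `trial_template()`, `generate_trial()`, `seven_trial_presets()` |
| design & reporting | `design_config()`, `design_report()`, `simulate_oc()`, CSV/YAML/JSON I/O |

A thin command-line wrapper (`generate`, `design`, `replay`, `simulate`)
ships in `inst/cli/gsreplay.R`.

## Worked example

Design a three-interim futility-leaning monitoring plan for a
460-participant trial with a disability index (lower is better) at
3/6/9/12 months, then replay a synthetic trial in which the test arm is
truly 3 points worse:

```r
library(gsreplay)

template <- seven_trial_presets(effect = -3)$WOLLF
trial <- generate_trial(template, seed = 20)

des <- design_report(design_config(
  template$schedule, sigma_star = 25, rho_star = 0.5,
  setting = "b", n_interims = 3,
  accrual = planned_accrual(
    matrix(c(115, 84, 45, 20, 190, 136, 85, 74, 255, 217, 173, 156),
           3, 4, byrow = TRUE),
    c(420, 400, 390, 380), labels = modelled_labels(template$schedule))))
des
#> Design report (setting b, 3 interims)
#>   expected information I*: 1=0.011, 2=0.037, 3=0.071, final=0.157
#> Group sequential boundaries (3 interims)
#>   look  info  lower upper
#> 1    1 0.011 -0.994 3.090
#> 2    2 0.037 -0.666 2.637
#> 3    3 0.071 -0.299 2.491
#>   final: info = 0.157, critical value = 2.071

replay(trial, des$bounds)
#> Group sequential replay
#> Window of opportunity: 2013-08-05 to 2015-09-16
#>   interim 1 (2013-08-05, month 13): beta = -14.41, Z = -1.54, I = 0.011 (planned 0.011), [-0.99, 3.09] -> stop_futility
#>   overrunning: beta = -6.46, Z = -1.48, I = 0.053
```

Reading the output: the window of opportunity opened 13 months in, once
enough primary outcomes existed to monitor information; the first interim
triggered as soon as observed information reached the planned 0.011; the
standardized statistic $Z = -1.54$ fell below the futility boundary
$l_1 = -0.99$, so the trial stops for futility with 201 of 460
participants recruited. The overrunning analysis — complete eventual
follow-up of everyone already recruited — agrees qualitatively
($\beta = -6.5$, still favouring control). Note the full-model estimate
can disagree with the raw primary-only difference at an early interim
(here $\beta 0$ was positive on 12 primary outcomes while $\beta$ was
clearly negative): the borrowing from strongly correlated early outcomes
is exactly what makes early interims informative.

Null operating characteristics of a design are verified by simulation:

```r
oc <- simulate_oc(template_null, bounds, n_reps = 20000, seed = 510)
```

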