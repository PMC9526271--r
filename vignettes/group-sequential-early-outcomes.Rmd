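---
title: "Group sequential designs informed by early longitudinal outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group sequential designs informed by early longitudinal outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(gsreplay)
```

## The problem

Pragmatic two-arm trials of surgical and other complex interventions
typically follow participants with a patient-reported outcome measure
(PROM) at several scheduled occasions — say 3, 6 and 12 months after
randomization — with one occasion designated the primary endpoint. Because
recruitment is slow and follow-up long, analyses restricted to the primary
outcome usually cannot inform a stopping decision before recruitment has
already finished. But PROM scores are strongly correlated within a
participant across occasions (correlations of 0.5–0.9 are typical), so
early outcomes carry real information about the primary-time treatment
effect. A longitudinal model that uses *all* outcome data accumulates
statistical information much faster than the primary outcome alone, and
that is what makes group sequential monitoring feasible in this setting.

`gsreplay` implements the full workflow: the longitudinal estimator, the
error-spending boundary construction, design-stage information planning,
calendar-time replay of a dated trial with biweekly monitoring, and a
synthetic trial generator used both for testing and for operating
characteristics.

## The outcome model

For participant $i$ let $Y_i$ be the vector of PROM values at the modelled
occasions $s = 1, \dots, t$ (occasions collected *after* the primary time
are excluded from the model). The model is

$$ Y_i \sim \mathrm{MVN}\left(\mu_{a(i)}, \Sigma\right), $$

with a saturated mean per arm per occasion and one unstructured covariance
matrix $\Sigma$ shared by the arms. The treatment effect is the
primary-time contrast $\beta_t = \mu_{\mathrm{test},t} -
\mu_{\mathrm{control},t}$, oriented so positive favours the test arm, with
standardized statistic $Z = \beta_t / \mathrm{sd}(\beta_t)$ and information
$I = 1/\mathrm{var}(\beta_t)$. A comparison analysis forces all
correlations to zero — equivalently, uses primary-outcome data only — and
its quantities are written $\beta 0_t$, $Z0$, $I0$. With complete
follow-up the two analyses coincide; with participants who have early but
not yet primary outcomes, the full model is strictly more informative
whenever the correlations are non-zero.

Estimation is by direct maximum likelihood over the observed-missingness
patterns (missing at random), implemented as an EM algorithm
(`fit_mvn_longitudinal()`). The variance of $\beta_t$ is the plug-in
generalized-least-squares variance at $\hat\Sigma$ given the observed
patterns — the same formula the planner uses with the design-stage
$\sigma^*, \rho^*$ treated as known — rather than a full observed-Fisher
variance. This keeps observed and expected information directly
comparable; it is a documented swap point should a sandwich or
observed-information variance be preferred. Two further conventions:
$\hat\Sigma$ uses the maximum-likelihood $1/n$ divisor (no small-sample
inflation), and a correlation between two occasions with no jointly
observed participants is started at zero with a warning since the
likelihood cannot identify it.

## Planning information levels

At the design stage the trial team fixes (i) the number of interim
analyses (one to three), (ii) expected standard deviations $\sigma^*$
(from the protocol sample-size calculation) and a common expected
correlation $\rho^* = 0.5$, and (iii) the number of participants expected
to have provided each outcome at each interim. `expected_information()`
converts these into the expected information $I^*_k$ that triggers each
interim, using the known-covariance GLS variance under monotone
(staged-follow-up) patterns and 1:1 allocation. For a single-occasion
design this is the familiar closed form $I^* = n / (2\sigma^{*2})$ per
arm-pair:

```{r}
acc <- planned_accrual(c(40, 80), 170, labels = "6m")
expected_information(acc, covariance_model(c(`6m` = 9), matrix(1, 1, 1)))
```

## Spending boundaries

Stopping is governed by cumulative error spending: by interim $k$ the
design will have stopped for futility with probability $\alpha^*_l(k)$ and
stopped rejecting the null (efficacy) with probability $\alpha^*_u(k)$,
both computed under the null; at the final analysis these reach exactly
0.975 and 0.025. Four futility presets (a)–(d), from conservative to
aggressive, are built in (`make_spending_plan()`); their efficacy spends
are deliberately tiny at interims, reflecting designs meant to stop early
mainly for futility.

`compute_boundaries()` solves for the critical values $l_k < u_k$ under
the canonical joint law of sequential statistics —
$\mathrm{cov}(Z_j, Z_k) = \sqrt{I_j/I_k}$ — by propagating the subdensity
of continuing paths across looks and root-finding each boundary so the
incremental exit probability equals the incremental spend. Numerical
choices: 256 Gauss–Legendre nodes per continuation interval, root finding
to $10^{-12}$ on the Z scale (well below the $10^{-8}$ probability
tolerance verified in the tests), futility boundaries binding, the upper
boundary solved before the lower at each look (the order is immaterial at
these tolerances; it is fixed for reproducibility). The first look needs
no grid — its boundaries are marginal normal quantiles. A useful
consequence of binding futility with the plan invariant
$\alpha^*_l(k) + \alpha^*_u(k) < 1$ is that solved boundaries can never
overlap; the solver still guards against it defensively.

```{r}
b <- compute_boundaries(make_spending_plan("b", 2), c(0.123, 0.247, 0.525))
b
exit_probabilities(b, drift = 0)  # reproduces the spending plan
```

## Replaying a dated trial

`replay()` walks the trial in calendar time. Monitoring begins once a
minimum-data rule holds — at least 5 participants per arm with a primary
outcome and an estimable primary SD (the rule is a package choice; the
requirement is only that "sufficient data" exist) — and repeats every 14
days until recruitment ends; this is the *window of opportunity*, which
can be empty when follow-up is long relative to recruitment (the
five-year-primary preset below). At each monitoring date the model is
fitted to the snapshot of data dated on or before that date; when observed
$I$ reaches the next planned $I^*_k$ the interim is conducted and $Z$
compared with $(l_k, u_k)$. Boundaries are *not* re-solved at the observed
information: the design levels are used as planned, mirroring practice
where interims simply occur earlier or later than expected as the
covariance estimates deviate from $\sigma^*, \rho^*$. If several
thresholds are passed between monitoring dates, the pending interims are
conducted in order at the same date. Triggering always uses the full-model
$I$; $I0$ is logged for comparison. Months are reported as days/30.44,
rounded. Decision latency (data cleaning, committee meetings) is not
simulated.

After a stop, `overrun_analysis()` refits on the complete eventual
follow-up of everyone recruited by the stop date — what the trial would
eventually have concluded about those already randomized.

```{r}
template <- seven_trial_presets(effect = -3)$WOLLF
trial <- generate_trial(template, seed = 20)
des <- design_report(design_config(
  template$schedule, sigma_star = 25, rho_star = 0.5,
  setting = "b", n_interims = 3,
  accrual = planned_accrual(
    matrix(c(115, 84, 45, 20, 190, 136, 85, 74, 255, 217, 173, 156),
           3, 4, byrow = TRUE),
    c(420, 400, 390, 380), labels = modelled_labels(template$schedule))))
res <- replay(trial, des$bounds)
res
```

## The synthetic generator

`generate_trial()` draws randomization dates from a piecewise-constant
Poisson process (supporting slow-pilot-then-ramp profiles), allocates 1:1
by permuted blocks of two (near-exact balance, as in the emulated trials),
draws each participant's outcome vector from the template's MVN truth,
jitters assessment dates around the nominal offsets, then applies monotone
dropout (a dropped participant contributes no later occasions) followed by
intermittent MCAR deletion, which adds the non-monotone holes that
exercise the general-pattern likelihood. Everything is reproducible from
the seed, down to byte-identical CSV output.

`seven_trial_presets()` provides templates emulating the published
*configurations* of seven surgical RCTs — sample sizes, schedules, score
orientations, recruitment spans, protocol SDs — with plausible
moderate-to-strong correlations and recovery-shaped mean trajectories.
Missingness is set so roughly 10–20% of participants lack the primary
outcome. These are synthetic stand-ins: the real trials' individual-level
data are not publicly available, so their observed effect estimates are
deliberately *not* encoded as truth, and nothing in the package attempts
to regenerate them.

What passing tests on these synthetic trials do show: the estimator,
planner, boundaries and replay machinery are mutually consistent, and the
designed error-spending is actually delivered by the end-to-end pipeline.
What they cannot show: robustness to features real PROM data possess and
the generator does not — informative (MNAR) missingness, floor/ceiling
effects and discreteness of the scores, site effects, and secular drift in
recruitment or outcome quality.

## Operating characteristics

`simulate_oc()` wraps generate→replay loops. By default it uses the
replay's known-covariance mode with the template's true covariance: the
statistics are then exactly standard normal under the null and, because
interim triggering depends only on assessment *dates*, the first-look
stopping fraction equals the spent probability exactly, with later looks
deviating only through the small mismatch between realized and planned
information ratios. This mode is also what keeps 20,000-replication runs
fast. Setting `use_template_cov = FALSE` exercises the maximum-likelihood
fit at every monitoring date instead — closer to practice, and slower.

The simulation sizes used in the package's own checks (20,000 null
replications per setting for spending verification, $10^6$ Monte-Carlo
paths for boundary verification, 2,000 per arm for parameter recovery)
were chosen so that three-standard-error checks are decisive at the
printed precision of the quantities being verified.

```{r, eval = FALSE}
oc <- simulate_oc(tm_null, bounds_a1, n_reps = 20000, seed = 510)
oc$table$p_futility[1]  # ~0.160 under setting (a) with one interim
```

## Known limitations

* Covariate adjustment (e.g. baseline-score ANCOVA), binary/ordinal
  outcomes and multi-arm designs are out of scope; so is any bias
  adjustment of the effect estimate for the interim looks — the package
  reports unadjusted estimates and stopping decisions only.
* One covariance matrix is shared by the arms; arm-specific $\Sigma$ is
  not supported.
* Sample-size inflation to retain power under early stopping is not
  computed; the planner takes accrual as given.
* Futility boundaries are always binding; a non-binding variant would
  spend efficacy differently.
* MAR is assumed throughout; no MNAR sensitivity analyses.
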