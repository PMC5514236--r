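# adaptod

Simulation of **model-based adaptive optimal design (MBAOD)** for a
dose-finding PKPD trial: should the next cohort's dose be optimized with
a *local* criterion (lnD: maximize `ln|FIM(Θ, ξ)|` at the current
parameter guess) or a *robust* one (ELD/API: maximize
`E_Θ[ln|FIM(Θ, ξ)|]` over a normal prior on the fixed effects)? The
package runs the whole adaptive loop in silico — optimize, enroll,
estimate, test a stopping rule — and measures how quickly each
criterion's designs approach the design one would pick knowing the
truth.

It is aimed at pharmacometricians and design methodologists who want a
self-contained, reproducible testbed for adaptive optimal design ideas
without a NONMEM/PsN toolchain.

## What is inside

* **Model** — sigmoidal Emax response (baseline, EMAX, EC50, Hill
  coefficient γ) driven by one-compartment first-order absorption PK
  (warfarin-like, fixed); log-normal between-subject variability on
  EMAX, EC50, CL, V; combined additive + proportional residual error.
* **Fisher information** — FO linearization (`fo_moments()`), elementary
  and population FIMs in block-diagonal and full form
  (`elementary_fim()`, `population_fim()`), plus a generic assembler
  (`fim_from_moments()`).
* **Design criteria** — `lnd_objective()`, `eld_objective()` with Latin
  hypercube prior integration, and an exhaustive integer-dose scan
  (`optimize_next_dose()`, 0–500 mg).
* **Estimation** — in-package FO and FOCEI-type maximum likelihood
  (`fit_nlmem()`), observed-information covariance
  (`estimate_covariance()`), broom-style `tidy()`/`glance()`.
* **Stopping rule** — multivariate-t parameter uncertainty
  (`sample_fixed_effects()`, df tied to the cumulative sample size);
  stop when the simulated 95% CI of the typical effect prediction lies
  within 60–140% of the predicted mean at every dose and sampling time.
* **Evaluation** — efficiency `(|FIM_test|/|FIM_ref|)^(1/P)` against the
  true-parameter reference trajectory, replicate summaries and ggplot2
  figures (`summarize_replicates()`, `plot_efficiency()`, ...).

A thin CLI lives in `inst/cli/adaptod.R`
(`adaptod.R run --config ... --out ...`, `adaptod.R report DIR --out ...`).

## Worked example

One adaptive replicate under the robust criterion, sparse sampling, the
built-in +50% misspecified initial guess:

```r
library(adaptod)

cfg <- mbaod_config(criterion = "ELD", schedule = "sparse",
                    max_cohorts = 10, n_stop_sim = 5000, seed = 7)
h <- run_mbaod(cfg, replicate = 4)
glance(h)
#> # A tibble: 1 × 5
#>   criterion schedule cohorts  n_id status
#>   <chr>     <chr>      <int> <int> <chr>
#> 1 ELD       sparse         2    10 stopped

tidy(h)[, c("cohort", "dose", "n_id", "base", "emax", "ec50", "gamma", "stopped")]
#> # A tibble: 2 × 8
#>   cohort  dose  n_id  base  emax  ec50 gamma stopped
#>    <int> <int> <int> <dbl> <dbl> <dbl> <dbl> <lgl>
#> 1      1    NA     8 0.969  109.  6.90  1.92 FALSE
#> 2      2    13    10 0.974  109.  7.17  1.91 TRUE
```

Cohort 1 is the fixed initial design (0 and 160 mg, 4 + 4 subjects);
the fitted curve is already close to the truth (1, 100, 7, 2), the
optimized cohort-2 dose lands at 13 mg (near the information-optimal
low-dose support point), and the effect-prediction stopping rule is
satisfied with 10 subjects.

Comparing criteria over 10 replicates each (≈3 min):

```r
res <- lapply(c("lnD", "ELD"), function(cr) {
  cfg <- mbaod_config(criterion = cr, schedule = "sparse",
                      max_cohorts = 10, n_stop_sim = 5000, seed = 7)
  summarize_replicates(run_replicates(cfg, 10, quiet = TRUE))
})
sapply(res, function(s) quantile(subset(s$efficiency, cohort == 2)$efficiency))
```

In this run the cohort-2 design efficiency (relative to the
true-parameter lnD reference) had median 0.59 with IQR 0.60 under lnD
versus median 0.89 with IQR 0.57 under ELD — averaging the criterion
over the parameter prior keeps a wild first-cohort fit from dragging
the second cohort's dose far from the optimum. `plot_efficiency()`,
`plot_dose_histogram()`, `plot_ree()` and `plot_sample_size()` render
the standard summary figures.

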