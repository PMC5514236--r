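---
title: "Model-based adaptive optimal design of a dose-finding PKPD trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based adaptive optimal design of a dose-finding PKPD trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptod)
library(dplyr)
```

## The problem

When a dose-finding study is designed up front, the design is only as
good as the prior guess of the model parameters. Model-based optimal
design picks the design that maximizes the Fisher information matrix
(FIM) of a nonlinear mixed-effects model (NLMEM), but a misspecified
parameter guess yields a misspecified "optimal" design. Two remedies are
combined in this package:

* **adaptation** — the study enrolls small cohorts; after each cohort the
  model is re-fitted to all accumulated data and the next cohort's dose
  is optimized under the updated guess;
* **robustness** — instead of optimizing at a point guess (the local
  `lnD` criterion, $\max_\xi \ln|\mathrm{FIM}(\Theta,\xi)|$), the
  objective can be averaged over a normal prior on the fixed effects
  (the `ELD`, also called API, criterion,
  $\max_\xi E_\Theta[\ln|\mathrm{FIM}(\Theta,\xi)|]$).

`adaptod` simulates such model-based adaptive optimal designs (MBAOD)
end to end — design optimization, patient simulation, estimation,
stopping — and measures how quickly the adapted designs approach the
design one would have chosen knowing the true parameters.

## The model

The response is a sigmoidal Emax pharmacodynamic model driven by the
concentration of a one-compartment, first-order absorption PK model
(warfarin-like parameters, fixed and not estimated):

$$C(t) = \frac{D\,k_a}{V k_a - CL}\left(e^{-(CL/V)t} - e^{-k_a t}\right),
\qquad
E(C) = \beta_{Base} + \frac{C^{\gamma}\,\beta_{E_{max}}}{C^{\gamma} +
\beta_{EC_{50}}^{\gamma}}.$$

EMAX, EC50, CL and V carry log-normal between-subject random effects
with diagonal covariance; the residual error is combined additive and
proportional, $y = E\,(1+\varepsilon_{prop}) + \varepsilon_{add}$.
Negative simulated observations are retained — nothing is censored.

The study scenario is built in (`scenario_parameters()`): true values
$\beta = (Base\,1,\ E_{max}\,100,\ EC_{50}\,7,\ \gamma\,2)$ with
$CL = 0.15$ L/h, $V = 8$ L, $k_a = 1$ h$^{-1}$;
$\omega^2 = (0.0625, 0.0625, 0.07, 0.02)$ for (EMAX, EC50, CL, V);
$\sigma^2_{add} = 0.001$, $\sigma^2_{prop} = 0.015$. The initial guess
overstates every PD fixed effect by 50% (1.5, 150, 10.5, 3). Seven
parameters are estimated: the four PD fixed effects,
$\omega^2_{EMAX}$, $\omega^2_{EC50}$ and $\sigma^2_{prop}$; everything
else is treated as known ("FIX").

Units are hours, mg and mg/L throughout; there is no unit-conversion
layer.

## Fisher information

`fo_moments()` linearizes the model at $\eta = 0$, $\varepsilon = 0$
(the FO approximation): the group mean is the typical prediction and the
variance is $L\,\Omega\,L' + \mathrm{diag}(\sigma^2_{prop} f^2 +
\sigma^2_{add})$ with $L$ the response Jacobian in $\eta$.
`elementary_fim()` assembles the per-subject information over the
estimated parameters only — FIX parameters are excluded from
differentiation entirely, not zeroed. The default is the block-diagonal
form (fixed-effect block $(\partial E/\partial\beta)' V^{-1} (\partial
E/\partial\beta)$, variance block
$\tfrac12\mathrm{tr}(V_a V^{-1} V_b V^{-1})$, zero off-diagonals), which
is the form the design criteria maximize; a `full` form keeps the
variance's sensitivity to the fixed effects and the mixed block. The
mixed block of the full form is the standard cross derivative
$\mathrm{tr}(V_{\beta_a} V^{-1} V_{\lambda_b} V^{-1})$ — the only
form that is dimensionally consistent when the numbers of estimated
fixed effects and variance parameters differ, as they do here (4 vs
3). The population FIM is the group-size-weighted sum of elementary
FIMs.

Derivatives are central finite differences with relative step `1e-5`
(absolute floor `1e-8`; `1e-5` for $\eta$ at zero). The model is smooth
and cheap, so finite differences are accurate to ~1e-10 relative and
avoid symbolic machinery; the test suite cross-checks every assembly
against Richardson-extrapolated derivatives (numDeriv) and closed forms.
The dose grid scan uses a vectorized evaluation that exploits the
linearity of concentration in dose; it is pinned to the reference path
at 1e-8 by a test.

## Dose optimization

The dose is a discrete covariate on an integer grid (0–500 mg).
`optimize_next_dose()` evaluates the criterion exhaustively for the
cumulative design plus one candidate group at every grid dose — on this
one-dimensional discrete space an exhaustive scan guarantees the global
optimum and doubles as its own certificate (the full trace is returned).
Ties break toward the lowest dose.

For ELD, the prior expectation is approximated with 10 Latin hypercube
samples (`lhs_sample()`, one draw per equal-probability stratum per
margin). The same draws are reused for every candidate dose (common
random numbers), so dose comparison is not perturbed by Monte-Carlo
noise. The prior is an untruncated independent normal per estimated
fixed effect; draws that violate positivity are redrawn within their
stratum, and a stratum that cannot produce a positive value is clamped
to a tiny positive number. A sampled parameter vector whose FIM is
singular at *every* candidate dose carries no design information and is
dropped from the average (the count is reported); a dose-specific
singularity still demotes that dose to $-\infty$. The criterion's log
determinant is computed by LU factorization, which stays finite for
near-singular information matrices — important in early cohorts, when
the fitted parameters can be extreme and a Cholesky-based
$-\infty$-for-everything would erase the dose ranking.

The first ELD prior uses a 10% coefficient of variation around the
initial guess; after each cohort the prior mean moves to the estimates
and the standard deviations to the square roots of the diagonal of the
estimated fixed-effect covariance. A degenerate (all-zero sd) prior is a
point prior and stays one, which keeps ELD exactly equal to lnD in
zero-uncertainty configurations.

## Estimation

`fit_nlmem()` maximizes an approximate marginal likelihood with
`stats::optim` (Nelder-Mead, then BFGS polish) on a transformed scale:
log for EMAX, EC50, $\gamma$ and all variance parameters, identity for
the baseline. Two approximations are provided:

* **FO** — subjects are marginally normal with the `fo_moments()` mean
  and variance; subjects sharing a group reduce to cheap per-group
  matrix algebra. This is the approximation the FIM itself uses, so
  design and estimation are mutually consistent, and it is the adaptive
  loop's default.
* **FOCEI** — a Laplace-type approximation expanded at each subject's
  empirical-Bayes mode with interaction (residual variance at the
  conditional prediction) and a Gauss-Newton inner Hessian.

On failure the fit restarts up to 3 times from 10%-jittered inits
(seeded); if everything fails the result is flagged unconverged and the
adaptive loop continues with the last successful estimates. The
fixed-effect covariance is the inverse of the observed information
(finite-difference Hessian of the objective at the optimum, delta-method
mapped to the natural scale, $\beta$ block extracted after full
inversion). A non-positive-definite Hessian is repaired by clipping
eigenvalues at 1e-10 and flagged; a repaired covariance is not used to
update the ELD prior.

### Known estimator bias

Both approximations are *approximate* likelihoods, and at this
scenario's between-subject variability ($\omega^2 = 0.0625$) they carry
visible asymptotic bias: with rich sampling and 500 subjects the FO
estimates of $E_{max}$ and $\gamma$ are biased by about +7% and −12%,
while the FOCEI/Laplace estimates show roughly +1–6% ($EC_{50}$) and
+8–14% ($\gamma$) on test datasets — the two families err in opposite
directions around the truth. This is a property of the approximations,
not a defect of the optimizer (baseline and EC50 recover to ~2% under
FO, and the suite verifies exact recovery as noise vanishes). Users who
need unbiased point estimates at high BSV should treat the reported
fixed effects accordingly; within the adaptive loop the bias matters
less, because design optimization only needs parameters in the right
region.

## Stopping criterion

After each cohort, `n_stop_sim` fixed-effect vectors are drawn from a
shifted multivariate t located at the estimates with scale
$S = \mathrm{COV}_{\hat\beta}\,(df-2)/df$ and
$df = n_{ID} - (n_{\hat\beta} + n_{\hat\lambda}/2)$, so the draw
covariance equals the estimated covariance (the scale-matrix convention
of `mvtnorm::rmvt`). Each draw yields a typical-individual effect
profile at every dose arm and sampling time included so far; the study
stops when the empirical 95% CI at every point lies within 60–140% of
the reference prediction (closed intervals, with a relative-epsilon
guard). Choices made where the procedure was open:

* the band reference is the prediction at the *estimates* — the truth is
  unknown to a running trial; each report row carries the reference so
  the alternative is recomputable;
* stopping is evaluated from cohort 1 onward, but deferred while
  $df \le 2$ (no finite covariance) or before any converged fit exists;
* a zero reference makes the band undefined: the point fails with a
  warning (the dose-0 arm's reference is the baseline, ~1, so this does
  not occur in the scenario);
* negative t draws (possible with heavy tails at small $df$) are clamped
  to a tiny positive value before prediction, and the stable ratio form
  of the Hill function keeps extreme draws finite;
* the full-scale default is 100,000 draws; the test profile uses 5,000,
  for which the 2.5%/97.5% empirical quantiles of a t-like variate have
  standard error below 2% of the CI width — immaterial against the 40%
  band.

## The adaptive loop and its study conditions

`run_mbaod()` wires the pieces together: cohort 1 is the fixed,
unoptimized initial design (0 and 160 mg, four subjects each); each
later cohort adds one group of two subjects at the optimized dose;
subjects are always simulated at the true parameters; estimation uses
all accumulated data; at most 50 cohorts. All randomness derives from
`(master seed, replicate, cohort, purpose)` so adding cohorts never
perturbs earlier data and replicates are exactly reproducible and
order-independent.

`reference_trajectory()` produces the comparator: the same cohort
structure optimized by lnD at the *true* parameters with no estimation.
Design efficiency is the per-parameter determinant ratio
$(|\mathrm{FIM}_{test}|/|\mathrm{FIM}_{ref}|)^{1/P}$ with both FIMs
evaluated at the true parameters, $P = 7$. `summarize_replicates()`
reports the 2.5th/50th/97.5th efficiency percentiles per cohort (the
symmetric 95% interval), the sample-size distribution, the optimized
dose histogram with the reference selections alongside (cohort-1 fixed
doses excluded), and the final-estimate relative errors. Replicates
that stop early carry their final design forward into later cohorts'
percentiles (flagged `carried`); `carry_forward = FALSE` gives the
survivors-only view. Because stopped designs stop growing while the
reference keeps adding optimal groups, carried-forward efficiencies
decline with cohort index — that is a property of this definition, not
of the designs.

## What the simulations show, and their limits

At the scaled-down study conditions used by the tests and the
acceptance script (10 replicates per criterion, sparse schedule, at
most 10 cohorts, 5,000 stopping draws — sizes chosen so the whole
comparison runs on a laptop in minutes), the robust criterion
reproduces the qualitative behavior expected of it: cohort-2 design
efficiencies are markedly less variable across replicates under ELD
than under lnD, because averaging the criterion over the parameter
prior prevents over-committing to a wild first-cohort fit.

The generator emulates exactly the scenario's conditions: parametric
log-normal BSV, diagonal covariance, a combined error model, perfect
compliance, no dropout, no model misspecification (the fitted model is
the generating model), and dose as the only covariate. Passing tests
therefore say nothing about robustness to structural model error,
covariate effects, or non-normal random effects — only about the
design-criterion machinery under the stated conditions. The
first-cohort fit is genuinely weakly identified (three PD curve
parameters from two dose arms and three sampling times), and wild
ridge estimates in early cohorts are part of the phenomenon being
studied, not an error state.

## Worked example

```{r example, eval = FALSE}
cfg <- mbaod_config(criterion = "ELD", schedule = "sparse",
                    max_cohorts = 10, n_stop_sim = 5000, seed = 7)
histories <- run_replicates(cfg, 10, quiet = TRUE)
s <- summarize_replicates(histories)
s$percentiles
plot_efficiency(s)
```
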