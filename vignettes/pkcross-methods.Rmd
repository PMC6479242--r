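---
title: "Methods: noncompartmental, bioequivalence, and compartmental machinery in pkcross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noncompartmental, bioequivalence, and compartmental machinery in pkcross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkcross)
library(dplyr)
```

pkcross implements the analysis chain of single-dose crossover
pharmacokinetic (PK) studies of an evening-dosed delayed-release and
extended-release (DR/ER) oral stimulant: noncompartmental analysis
(NCA) of plasma concentration–time profiles, average bioequivalence
(ABE) on log-transformed exposure metrics, and a one-compartment
absorption-lag model used to predict accumulation under repeated
dosing. Because subject-level data from such programs are rarely
published, the package ships a seeded generator of synthetic crossover
studies with the statistical structure the analyses assume; every
pipeline stage is exercised against analytic oracles and that
generator. This vignette records the models, the defaults and their
units, the numerical choices, and what the synthetic studies do and do
not establish about real data.

## Data model and the LLOQ rule

Studies are long-format tables (`subject`, `sequence`, `period`,
`treatment`, `time_h`, `conc_ng_ml`), the NONMEM-style convention for
PK datasets, bundled with per-treatment regimens (dose in mg,
formulation, dosing interval) by `pk_study()`. Times are hours
post-dose; clock times never enter computation, and the predose sample
is recorded as time 0. Concentrations below the assay lower limit of
quantitation (LLOQ, default 0.02 ng/mL) are replaced by exactly zero on
construction — the analysis operates on substituted values only, and
the raw value is not retained. The substitution is idempotent, which
the suite checks as a property. CSV round-tripping writes numerics with
17 significant digits and re-reads them with base R's correctly rounded
parser, so a written study is bit-identical on re-read.

## Noncompartmental analysis

Per profile, `nca()` reports `Cmax` and `Tmax` (earliest time at the
maximum; ties broken to the earliest, a deterministic convention),
`AUC0–t` by the linear trapezoidal rule to the last quantifiable
concentration, `AUC0–∞ = AUC0–t + Clast/λz`, the terminal rate constant
λz, half-life `t½ = ln 2/λz`, dose-normalised `Cmax` and `AUC0–t`, and
the early-exposure fraction (share of `AUC0–t` accrued before 10 h —
for an evening-dosed DR/ER formulation this is the overnight release).

Two choices deserve comment because standard NCA software leaves them
configurable:

* **λz window selection.** The terminal regression uses points strictly
  after `Tmax`, excludes zeros (log undefined; they stay in the
  trapezoid), and evaluates every suffix window of at least 3 usable
  points ending at the last positive concentration. The window with the
  largest adjusted R² wins; ties go to more points. This mirrors the
  "best fit" behaviour of WinNonlin-class tools. The search is computed
  with suffix cumulative sums, so dense profiles (thousands of points)
  cost O(n). A manual per-profile window override is supported. When no
  window has a negative slope the metric is reported missing rather than
  forced.
* **Early-exposure denominator.** The denominator is `AUC0–t`, not
  `AUC0–∞`: it is always defined, and the extrapolated share of exposure
  is a few percent for these profiles, so the distinction is immaterial;
  the window and the denominator are both arguments.

Arm summaries report arithmetic mean, CV% with the sample (n−1) SD —
the clinical-PK reporting convention — median, range and geometric
mean. Mean t½ is the mean of per-subject values, so summaries do not
(and must not) enforce `mean t½ = ln 2/mean λz` across subjects.

## Average bioequivalence

`crossover_be()` fits the crossover model on the natural log of an
exposure metric with sequence, period and treatment effects and a
subject effect, then back-transforms: geometric LS means per treatment,
the test/reference ratio `exp(difference of LS means)`, its 90% CI
`exp(difference ± t[0.95, df]·SE)`, and the intrasubject CV
`100·sqrt(exp(σ²within) − 1)` from the residual variance. Equivalence is
declared when the CI lies inside 0.8–1.25, boundaries included. For the
three-condition Latin square all pairwise contrasts come from one model
fit with no multiplicity adjustment, matching how such tables are
reported.

For balanced complete data the model is fitted with subject as a fixed
effect (`lm`), which coincides with the REML mixed model there and is
the textbook ABE computation; the CI uses the residual degrees of
freedom (n − 2 in a balanced 2×2). Unbalanced data fall back to a
subject-random-intercept REML fit with Satterthwaite degrees of
freedom (`lmerTest`). LS means are computed by averaging model-matrix
rows over the reference grid of the remaining design factors, not from
raw cell means, so they are correct under period imbalance. The suite
proves the fixed-effects path equal to an independently coded
closed-form 2×2 crossover ANOVA (period-difference method) to 1e−8,
and property tests cover antisymmetry under contrast reversal, exact
scale equivariance, and invariance to additive period effects.
Geometric LS means are carried at full precision; the 3-decimal
rendering of `render_be_table()` happens only at display time.

## One-compartment absorption-lag model

The single-dose concentration is

$$C(t) = \frac{F D}{V}\,\frac{k_a}{k_a - k_e}
\left(e^{-k_e (t - t_{lag})} - e^{-k_a (t - t_{lag})}\right),
\qquad t > t_{lag},$$

and 0 before the lag, with `scale = F/V` in (ng/mL)/mg so the curve is
exactly linear in dose. When `|ka − ke| < 1e−8·ke` the removable
singularity is replaced by its limit
`scale·D·ka·(t−tlag)·exp(−ka(t−tlag))`, keeping the function continuous
in the parameters; an ODE integration of the gut→central system agrees
with the closed form to below 1e−6 ng/mL.

`fit_one_cpt()` minimises the unweighted residual sum of squares
against an arithmetic mean profile — a deliberate choice: the study
design this package mirrors fitted the mean PK profile, and naive
pooling keeps the machinery simple and fully testable, at the cost of
ignoring between-subject variability (which lives in the generator
instead). Fitting uses Levenberg–Marquardt on log-transformed rates and
scale with `tlag` bounded in [0, first positive time], and a
deterministic multi-start: `ke` from the NCA λz, `tlag` from the last
zero-concentration time, `scale` from the observed peak, and `ka` over
the grid {0.2, 0.5, 1, 2}/h. The multi-start guards the flip-flop
ambiguity — the biexponential is invariant under swapping `ka` and `ke`
with `scale` rescaled by `ka/ke` — and the returned ordering is the one
whose `ke` is closest to the NCA terminal slope, with the alternate
ordering exposed in the fit object. Noiseless self-generated curves are
recovered to 1e−4 relative (in practice machine precision).

`simulate_regimen()` builds multiple-dose profiles by superposition of
time-shifted single-dose curves on a 0.05 h grid (an upper bound of
0.1 h is enforced for extremum detection). Interval peaks are grid
maxima refined by local quadratic interpolation; troughs (`Cmin`) are
defined as the concentration exactly 24 h post-dose — not the
within-interval minimum — and are evaluated analytically at those
times. The closed-form steady state is the geometric-series limit

$$C_{ss}(t) = \frac{F D}{V}\frac{k_a}{k_a-k_e}\left(
\frac{e^{-k_e u}}{1-e^{-k_e \tau}} -
\frac{e^{-k_a u}}{1-e^{-k_a \tau}}\right),
\qquad u = t - t_{lag} \bmod \tau,$$

where the wrap of `u` carries the preceding dose's absorption into the
pre-lag part of the interval. Superposition and the closed form agree
to 1e−6 over a 50-dose interval, so either route may be used.
Accumulation ratios divide the final-interval (steady-state) peak or
trough by the first-dose value; steady state is declared at the first
dose whose trough is within 1% of the closed-form trough. With
absorption complete within the interval, the trough ratio reduces to
`1/(1 − exp(−ke·τ))` — about 1.06 at `ke = 0.1192`/h and τ = 24 h,
which is why a formulation with a 6 h half-life shows negligible
once-daily accumulation.

## The synthetic-study generator

`default_config()` encodes three study templates; their defaults are
the study conditions, chosen once from the designs they emulate, and
are not tuning knobs:

* **Dose proportionality**: 2×2 crossover, n = 20, 20 vs 100 mg of the
  delayed formulation, identical model parameters (proportionality by
  construction).
* **Evening food effect**: six-sequence 3×3 Latin square, n = 18,
  100 mg fed / sprinkled / fasted. Fed shifts the lag by +2.5 h and
  slows absorption (`ka` × 2/3, blunting the peak ≈ 12%) with
  elimination and total exposure unchanged; sprinkled equals fasted.
* **Relative bioavailability**: 2×2 crossover, n = 12, 100 mg delayed
  vs 20 mg immediate release, each arm on its own sampling schedule;
  delayed-formulation `scale` is set so its dose-normalised AUC0–∞ is
  73.9% of the immediate-release value.

The delayed population parameters (`ka` 0.45/h, `ke` 0.1192/h, `tlag`
10 h, `scale` 0.2 (ng/mL)/mg) put the noiseless peak at 14 h on the
sampling grid, the terminal slope at 0.1192/h, `Cmax` ≈ 12.3 ng/mL and
AUC0–∞ ≈ 168 ng·h/mL at 100 mg, with zero exposure before 10 h. The
immediate-release reference (`ka` 1.6/h, `ke` 0.191/h, no lag) peaks at
1.5 h on its grid. Sampling grids are the dense schedules such studies
use: twice-hourly around the expected release window (8–12 h) out to
48 h for the delayed formulation, front-loaded to 24 h for immediate
release.

Variability defaults: 30% lognormal between-subject CV on `ka`, `ke`
and `scale` (one draw per subject, shared across periods — subject is
the random effect of the crossover model), a truncated-normal lag
jitter (SD 0.5 h, floored at 8 h, sampled by inverse-CDF so no
rejection loop disturbs the stream) reflecting the tightly controlled
release delay, and residual error of 10% proportional CV plus an
additive SD equal to the LLOQ. These produce arm-level CVs of roughly
30–45% for `Cmax`/AUC and single-digit `Tmax` CVs, the ranges typical
of this formulation class. Draw order is fixed (all subject draws, then
all observation draws), so studies are bit-reproducible from the seed.

`generate_true_ratio_study()` is the calibration harness: the test
treatment's population curve is the reference curve scaled by a known
ratio, and noise is purely multiplicative lognormal (per-subject and
per-profile), so the log-scale crossover model holds *exactly* and the
90% CI must cover the true ratio at its nominal rate. The suite runs
500 replicates (n = 18, intrasubject CV 20%) and requires coverage
within 90 ± 3%; the run takes about a minute.

What passing these tests shows — and does not. The generator emulates
lag-then-first-order absorption with lognormal variability; it does not
reproduce real features such as genuinely zero-order or mixed-order
release phases, enantiomer kinetics, circadian elimination, early
overnight micro-release (its noiseless early-exposure fraction is
exactly 0, where observed values in this formulation class are 1–4%),
or assay-level heteroscedasticity beyond the proportional+additive
model. Agreement on synthetic data therefore validates the estimators
and their calibration, not any claim about a particular real product.

## Numerical and design notes

* AUC windows interpolate boundary values linearly; AUC is additive
  over interior split points to 1e−12 and invariant to insertion of
  collinear points.
* Interior zero concentrations stay in trapezoids but never enter the
  log-linear regression.
* The no-accumulation limit (`τ` much larger than the washout) yields
  troughs that underflow to exact zero; accumulation ratios are then
  reported missing rather than 0/0.
* Problem sizes used by the tests and the acceptance script — studies
  of 12–24 subjects, 500-replicate coverage runs, 20-dose simulations,
  50-dose superposition checks — were chosen so the full chain
  demonstrates its properties in about a minute per stochastic block.
* The `parallel` design tag in `pk_study()` is accepted for data
  containers but the generator and BE machinery target the two crossover
  designs; parallel-arm inference is out of scope, as are
  replicate-design scaled ABE and nonparametric `Tmax` comparisons.

## A worked pipeline

```{r pipeline, eval = FALSE}
pipe <- run_pk_pipeline("dose_proportionality", seed = 1)
pipe$be_table       # geometric LS means, intrasubject CV%, ratio (90% CI)
pipe$accumulation   # single-dose vs steady-state Cmax/Cmin and ratios
autoplot(pipe$study)
autoplot(pipe$fit)
```
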