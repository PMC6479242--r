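# pkcross

Noncompartmental and bioequivalence analysis of crossover
pharmacokinetic (PK) studies, built around the analysis chain used for
evening-dosed delayed-release/extended-release (DR/ER) oral stimulant
formulations: a drug released after an ~10-hour lag, absorbed
monophasically to a mid-day peak, and eliminated with a terminal rate
constant near 0.12 h⁻¹.

The package is for PK scientists and statisticians who need the full
chain as composable, tested R functions:

* **Noncompartmental analysis** — `nca()` computes, per
  subject × period profile: Cmax, Tmax (earliest-time tie-break),
  AUC0–t by the linear trapezoidal rule, AUC0–∞ = AUC0–t + Clast/λz,
  the terminal rate constant λz (best-adjusted-R² window selection over
  terminal points after Tmax), half-life t½ = ln 2/λz, dose-normalised
  exposure, and the early-exposure fraction (% of AUC0–t before 10 h).
* **Average bioequivalence** — `crossover_be()` fits the crossover
  model on ln-transformed metrics (sequence, period, treatment effects;
  subject effect) for 2×2 and six-sequence 3×3 Latin-square designs and
  reports geometric LS means, the test/reference ratio with its 90% CI
  `exp(Δ ± t₀.₉₅,df·SE)`, intrasubject CV `100·√(exp(σ²within) − 1)`,
  and the 0.8–1.25 equivalence verdict.
* **One-compartment absorption-lag model** — `one_cpt_conc()`,
  `fit_one_cpt()` (Levenberg–Marquardt with deterministic multi-start
  on a mean profile), `simulate_regimen()` (multiple-dose
  superposition), `steady_state_conc()` (closed form), and
  `accumulation_ratio()` (steady-state / single-dose Cmax or 24-h
  trough).
* **Synthetic crossover studies** — `default_config()` +
  `generate_study()` simulate the three classic study templates (dose
  proportionality 20 vs 100 mg, evening food effect
  fed/sprinkled/fasted, relative bioavailability vs immediate release)
  with lognormal between-subject variability, proportional + additive
  residual error, and a 0.02 ng/mL LLOQ with below-limit values set to
  zero; `generate_true_ratio_study()` provides a calibration harness
  with an exactly known true ratio.

Everything is tibble-first and pipe-friendly; fitted objects support
broom-style `tidy()`/`glance()` and `autoplot()`.

## Worked example

```r
library(pkcross)

pipe <- run_pk_pipeline("dose_proportionality", seed = 1, n_doses = 10)
pipe$be_table
#>        metric     contrast gls_mean_test gls_mean_reference intra_cv_pct
#> 1     dn_cmax dr20 / dr100        0.1329             0.1334         5.53
#> 2 dn_auc_last dr20 / dr100        1.6040             1.6320         3.62
#>            ratio_ci90 within_limits
#> 1 0.996 (0.966–1.027)           yes
#> 2 0.983 (0.964–1.003)           yes
```

The generator's two arms share model parameters and differ only in
dose, so the true dose-normalised ratio is 1: the estimated geometric
LS mean ratios (0.996 and 0.983) sit near 1 with 90% CIs inside the
0.8–1.25 limits — dose proportionality is (correctly) declared, with
single-digit intrasubject CVs.

```r
pipe$fit
#> One-compartment absorption-lag fit
#> <one_cpt_params> ka 0.3965 /h | ke 0.1281 /h | tlag 9.898 h | scale 0.2108 (ng/mL)/mg
#> dose 100 mg | RSS 0.764098 | n 25 | converged: TRUE

dplyr::select(pipe$accumulation, dose_mg, cmax_single, cmax_ss, r_cmax,
              cmin_single, cmin_ss, r_cmin)
#>   dose_mg cmax_single cmax_ss r_cmax cmin_single cmin_ss r_cmin
#> 1      20        2.46    2.64   1.07       1.000    1.05   1.05
#> 2     100       12.3    13.2    1.07       5.00     5.25   1.05
```

The mean-profile fit recovers the generating parameters (lag ≈ 10 h,
terminal rate ≈ 0.12 h⁻¹), and once-daily multiple-dose superposition
predicts negligible accumulation: peak and trough ratios of about
1.05–1.07, the expected behaviour for a drug whose half-life (≈ 5.8 h)
is much shorter than the 24 h dosing interval.

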