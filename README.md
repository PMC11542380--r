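# alpkpd

Population pharmacokinetic (pop-PK) modelling and Monte-Carlo
dose-regimen simulation for total *Atractylodes lancea* (AL) bioactivity
in advanced-stage intrahepatic cholangiocarcinoma (iCCA).

The package is for pharmacometricians and trial statisticians who want to
go from concentration–time data (or a synthetic stand-in for them) to a
defensible phase-2B dose recommendation:

1. **Structural model** — one compartment, zero-order absorption of
   duration Tk0 without lag, linear clearance.  For a dose D at time 0:
   C(t) = D/(Tk0·CL) · (1 − e^(−ke·t)) during absorption and
   C(t) = D/(Tk0·CL) · (1 − e^(−ke·Tk0)) · e^(−ke·(t−Tk0)) afterwards,
   ke = CL/V, with multi-dose superposition and an independent
   numerical-integration oracle.
2. **Population layer** — lognormal/normal random effects per parameter
   (the kind assignment is pinned by consistency with the reported %CV
   columns), combined residual error y = f + (a + b·f)·ε, and bundled
   presets for the three fitted study occasions (day 1, day 14, day 28).
3. **Estimation** — stochastic approximation EM (SAEM) written for this
   package: Metropolis-within-Gibbs E-step, stochastically approximated
   M-step with variance annealing, importance-sampling OFV, AIC/BIC/BICc,
   forward covariate screening, goodness-of-fit tables and visual
   predictive checks.
4. **Simulation** — 1,000 virtual patients per occasion model, multi-dose
   Cmax over 90-day or 1-year courses, efficacy classified by the
   exposure thresholds Cmax ≥ 32.39 mg/L (tumor-progression inhibition)
   and ≥ 21.42 mg/L (death prevention), patient-level adherence gating
   (dose-level skipping as a sensitivity mode).
5. **Comparison & recommendation** — Woolf odds ratios, chi-square tests,
   number-needed-to-treat, and a capsule-count-aware dose selection rule.

A synthetic phase-2A trial generator (`generate_trial()`) reproduces the
study design (arms of 15/16/16, once-daily 1,000–2,000 mg, 12 sampling
times over 0–8 h) and serves as the test bed, since the clinical dataset
is not public.

## Worked example

```r
library(alpkpd)

# the three fitted occasion models (typical values, omegas, error pairs)
mods <- al_model_presets()
mods$table3_day28
#> <population_model> day28
#>   tk0 typical 0.95     omega 0.28    (lognormal, CV 28.6%)
#>   v   typical 32       omega 0.25    (lognormal, CV 25.4%)
#>   cl  typical 16.13    omega 0.38    (lognormal, CV 39.4%)
#>   residual error a = 2.21 mg/L, b = 0.084

# a typical day-28 patient on 2,000 mg peaks at the end of absorption
p <- structural_params(tk0 = 0.95, v = 32, cl = 16.13)
cmax(p, dose_schedule(0, 2000), window = c(0, 24))
#> $cmax
#> [1] 49.66364
#> $tmax
#> [1] 0.95

# simulate the candidate regimens (1,000 virtual patients, conjunction
# over the three occasion models) and pick a dose
spec <- simulation_spec(seed = 11)
eff <- simulate_efficacy(spec, doses_mg = c(1000, 1500, 2000, 2500, 3000),
                         adherence = 1, n_replicates = 50)
eff[, c("dose_mg", "progression_pct", "mortality_pct")]
#>   dose_mg progression_pct mortality_pct
#> 1    1000           100.0          87.7
#> 2    1500            88.5          21.9
#> 3    2000            41.4           3.8
#> 4    2500            12.3           1.1
#> 5    3000             3.9           0.4
```

The progression column is the percentage of virtual patients whose Cmax
stays below 32.39 mg/L under at least one occasion model (they are not
protected from progression); mortality reads the same way against
21.42 mg/L.  Higher doses push more of the population over both
thresholds, with diminishing returns past 2,500 mg — while the capsule
count keeps rising, which is what the recommendation rule trades off:

```r
recommend_dose(eff)
#> $dose_mg   [1] 2500
#> $capsules  [1] 23
```

On the calibrated reference efficacy series (`reference_efficacy()`, the
reported 100%-adherence base rates) the same rule also selects 2,500 mg.

`run_pipeline(pipeline_config(seed = 1, out_dir = "out"))` chains the
whole study flow — synthetic data, three SAEM occasion fits, validation
against the observed arm efficacies, the regimen × adherence grid,
contingency comparisons and the recommendation report — deterministically
from one seed.

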