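# gimend

Gene-informed microbial-enzyme decomposition modeling of soil heterotrophic
respiration under experimental warming.

## The problem

Soil heterotrophic respiration (Rh) — CO₂ released by microbial
decomposition of litter and soil organic matter — is the largest biological
carbon flux to the atmosphere after photosynthesis, and how its temperature
sensitivity (Q10) responds to sustained warming is a first-order
uncertainty in carbon–climate feedback projections. In long-term grassland
warming experiments, microbial communities *adapt*: the Q10 of Rh declines
under warming, so warmed plots respire less carbon than a
no-adaptation extrapolation predicts. Quantifying that effect requires
separating the direct temperature response from confounded drivers
(moisture, substrate), which is done by calibrating a process model
against field observations.

`gimend` implements that analysis end to end for desk-scale synthetic
data:

* **MEND** — a microbial-enzyme decomposition model: two particulate
  organic matter pools decomposed by oxidative and hydrolytic enzymes, a
  mineral-associated pool, Langmuir-sorbed and dissolved organic matter,
  active/dormant microbial biomass with explicit enzyme production,
  dormancy and mortality. Decomposition is Michaelis–Menten in substrate,
  linear in the enzyme pool, and scaled by Q10-temperature, moisture and
  pH response functions. The integrator closes the carbon budget to
  floating-point precision at every step.
* **TECO** — a first-order multi-pool (CENTURY-type) baseline:
  dX/dt = A ξ(T,W) K X + B I(t).
* **Multi-objective calibration** — J = Σ wᵢ Jᵢ with w = (5/8, 1/8, 1/8,
  1/8) over Rh (1 − R²), microbial biomass (MARE) and two functional-gene
  components (1 − r against annual gene-abundance indices under control;
  MARE against expected enzyme concentrations under warming). "gMEND" uses
  all four components, "tMEND" drops the gene components. Minimization by
  Shuffled Complex Evolution (SCE-UA); parameter uncertainty by the
  Critical Objective Function Index (COFI): all parameter sets with
  J < J_cr = J_min (1 + p/(n−p) F₁₋α(p, n−p)) form the 95% confidence
  region, sampled by uniform-over-region Metropolis chains. A Metropolis
  sampler for probabilistic (MCMC) inversion and AIC model comparison are
  included.
* **Thermal adaptation** — apparent Q10 by fitting
  R(T) = R(T_ref) · Q10^((T−T_ref)/10); the adaptation effect as
  %ΔRh = 100 · (Rh^woA − Rh^wA) / Rh^CT, where both warming fluxes are
  anchored at the control baseline and evaluated at the warming
  temperature with the control versus warming Q10; Monte-Carlo
  uncertainty from the COFI ensembles; single-factor temperature/moisture
  attribution; response ratios RR = ln(warming/control).
* **Synthetic data** — paired control/warming daily forcing (sinusoid +
  AR(1) soil temperature with a +2.8 °C warming offset, −6.4 % moisture,
  8-day-blocked GPP-derived carbon input) and noisy observations (74
  monthly Rh values, annual microbial biomass, annual gene indices
  proportional to simulated enzyme pools) generated from known
  parameters, so every stage is testable against a known truth.

## Worked example

```r
library(gimend)

forcing <- gen_forcing(years = 7, seed = 1)        # control + warming
control <- forcing_treatment(forcing, "control")
sim <- simulate_mend(control, mend_params(q10 = 1.77), dt = 0.25)
sim
#> <mend_sim> 2555 days, dt = 0.25 d
#>   mean Rh: 2.026 g C m-2 d-1
#>   max |C-balance residual|: 4.78e-13 mg C g-1
```

The simulated mean Rh (≈2 g C m⁻² d⁻¹) is a realistic temperate-grassland
heterotrophic flux, and the carbon-balance residual shows the budget
closes to machine precision. Fitting the apparent Q10 to synthetic
observations drawn from this simulation:

```r
obs <- gen_observations(control, mend_params(q10 = 1.77), n_rh = 74, seed = 2)
d <- data.frame(
  soil_temp = control$soil_temp[match(obs$rh_obs$date, control$date)],
  rh = obs$rh_obs$value)
fit_apparent_q10(d, t_ref = 10)
#> <q10_fit> Q10 = 1.344 +/- 0.0694 (nls, n = 74, p = 2.93e-08)
```

The apparent Q10 (1.34) is far below the model Q10 that generated the
data (1.77): moisture and substrate covary with temperature and confound
the direct response — exactly why the model-based inversion is needed.
The thermal-adaptation arithmetic at the mean calibrated sensitivities:

```r
adaptation_effect(q10_ctl = 1.77, q10_warm = 1.39,
                  t_ctl = 17, t_warm = 20, rh_baseline = 1.84)
#>   rh_ct rh_wa rh_woa delta_rh pct_delta_rh
#> 1  1.84 2.031  2.184    0.153          8.3
```

With adaptation, warming Rh is 2.03 g C m⁻² d⁻¹; without it 2.18; the
difference is an 8.3 % (8.2 % at the printed 2-decimal flux precision)
reduction relative to the control baseline — carbon that adaptation keeps
in the soil. The full pipeline — generate, spin up, calibrate both
treatments with SCE, filter COFI ensembles, propagate to %ΔRh — is one
call:

```r
res <- run_pipeline(pipeline_config(seed = 1, max_evals = 4000))
res$q10          # model-derived Q10 per treatment with 95% intervals
res$adaptation   # Monte-Carlo %ΔRh over the COFI ensembles
```

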