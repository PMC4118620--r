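# glycomca

Why do proliferating cells convert most of their glucose to lactate even when
oxygen is plentiful? **glycomca** is an R package for interrogating that
question — the Warburg Effect — with a mechanistic kinetic model of
glycolysis coupled to energy (ATP/ADP/AMP, creatine) and redox (NAD⁺/NADH)
metabolism. It provides:

- a 27-state ODE model of glycolysis with thermodynamically constrained
  reversible rate laws (every reversible step obeys the Haldane relation
  `Vrmax = Vfmax·Kmr/(Kmf·Keq)`, `Keq = exp(−ΔG°/RT)`), allosteric control
  (PFK ← F26BP/AMP/ATP, HK ← G6P, PK ← FBP, respiration ← ADP), facilitated
  and passive transport, lumped oxidative phosphorylation and a saturable
  mitochondrial NADH shuttle;
- Latin hypercube Monte Carlo exploration of enzyme-activity space
  (each capacity sampled over a 100-fold range around its baseline) with
  feasibility filtering: non-converged, non-positive, thermodynamically
  inconsistent, or locally unstable steady states are rejected with recorded
  reasons;
- metabolic control analysis: flux control coefficients
  `FCC_i = ∂ln J_lac/∂ln E_i` of every capacity on the lactate flux, with
  the summation theorem (`Σ FCC_i = 1`) as a per-realization quality gate,
  plus clustered FCC–FCC and FCC–metabolite correlation maps;
- Warburg statistics over the accepted ensemble: `W = J_lac/J_ox`, the
  lactate fraction `W/(1+W)`, correlation panels against metabolite levels
  and enzyme capacities, the bimodal fructose-1,6-bisphosphate (FBP) state
  split, and state-conditioned Spearman correlations of lactate flux;
- a ¹³C-lactate tracer pipeline: slope-based flux estimation with an
  R² > 0.98 linearity gate, occupancy-based dose → fraction-inhibited
  conversion, and empirical flux control coefficients from inhibitor
  dose–response panels;
- seeded synthetic-data generators (perturbation panels in the
  14-conditions × 3-replicates design, tracer time courses, in-silico
  dose–response panels) so the entire pipeline runs end-to-end without any
  external data.

All user-facing functions take and return tidy tables (tibbles), chain with
the pipe, and expose `tidy()`/`glance()`/`autoplot()` methods where a fitted
object is involved.

## Worked example

```r
library(glycomca)

model <- glycolysis_model()
model
#> <glyco_model> kinetic model of aerobic glycolysis
#>   state variables: 27 (23 dynamic, 4 boundary-constant)
#>   reactions: 24 (24 controllable steps)
#>   conserved pools: adenylate = 3.33 mM, NAD(H) = 0.505 mM, creatine = 10.5 mM

sol <- solve_steady_state(model)
round(sol$state[c("ATP", "FBP", "PYR", "LAC", "NADH")], 3)
#>   ATP   FBP   PYR   LAC  NADH
#> 3.214 0.602 0.015 1.225 0.008

warburg_effect(sol$fluxes[["LDH"]], sol$fluxes[["OXPHOS"]])
#> # A tibble: 1 x 2
#>       W lactate_fraction
#> 1  1.55            0.607
```

The baseline cell sits at 3.2 mM ATP and routes about 61% of its
pyruvate-derived flux to lactate (`W = 1.55`, mildly fermentative). Flux
control at this state lies mostly outside glycolysis proper:

```r
round(fcc_vector(model, sol$state,
                 steps = c("GAPDH", "PFK", "ATPASE", "OXPHOS")), 3)
#>  GAPDH    PFK ATPASE OXPHOS
#>  0.030  0.368  2.570 -1.810
```

ATP demand (`ATPASE`, positive) and mitochondrial capacity (`OXPHOS`,
negative) dominate lactate flux control — raising ATP turnover 1% raises
lactate output ~2.6%. Across the Monte Carlo ensemble the picture becomes
state-dependent: in realizations with millimolar FBP, GAPDH takes over as
the bottleneck separating upper from lower glycolysis.

```r
ens <- run_ensemble(model, n = 40, seed = 7)
ensemble_summary(ens)
#> # A tibble: 1 x 9
#>       n n_accepted acceptance_rate  none no_convergence negative_state ...
#> 1    40         29           0.725    29              3              8

acc <- accepted_realizations(ens)
round(100 * max(acc$lactate_fraction, na.rm = TRUE), 1)
#> [1] 93.9
```

Even 40 draws reach realizations sending ~94% of pyruvate-derived flux to
lactate; at the study scale (500+ draws) the maximum exceeds 95% and the
accepted `W` values span from below 1 (primarily oxidative) across more
than three orders of magnitude.

The tracer side mirrors the wet-lab flux measurement:

```r
tc  <- generate_tracer_timecourse(1.5, noise_sigma = 2, seed = 1)
fit <- fit_lactate_flux(tc)
glance(fit)
#> # A tibble: 1 x 5
#>   slope std_error r_squared linear_flag     n
#> 1  1.54    0.0302     0.999 TRUE            4
```

A labeled-lactate accumulation of 1.5 concentration-units/min is recovered
as 1.54 ± 0.03 with R² = 0.999, passing the linearity gate.

## A note on the default parameters

No per-reaction kinetic supplement is bundled from any single study: the
default parameter set is a curated, literature-plausible reconstruction
(documented value-by-value via `parameter_table()`), calibrated once so the
baseline steady state is feasible, thermodynamically consistent and sits in
the physiological ATP range. The methods vignette
(`vignettes/glycolysis-control.Rmd`) records the modeling assumptions,
calibration rationale and known limitations.
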