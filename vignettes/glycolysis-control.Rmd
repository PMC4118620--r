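---
title: "Modeling flux control in aerobic glycolysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling flux control in aerobic glycolysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the choices made where the design was genuinely open, the
numerical machinery, and what the synthetic-data generators do and do not
emulate.

## The model

The reference network tracks 27 time-dependent concentrations (mM): 23
intracellular species — the glycolytic intermediates from glucose to
lactate, fructose-2,6-bisphosphate, serine, the adenylates (ATP/ADP/AMP),
the pyridine nucleotides (NAD⁺/NADH), inorganic phosphate, creatine and
phosphocreatine, and dissolved oxygen — and 4 media species (glucose,
lactate, oxygen, serine). Media species are clamped to constant
concentrations by default, reflecting an excess-media culture; a
configuration switch (`media_dynamic = TRUE`) enables their dilution
dynamics, scaled by the cell-to-media volume ratio `r_ie` (default 0.01),
for tracer-style simulations.

Each intracellular species obeys a mass balance: transport flux plus the
stoichiometric sum of producing and consuming reactions. Three conservation
laws are built into the stoichiometry and verified by tests: the adenylate
pool (ATP+ADP+AMP), the pyridine-nucleotide pool (NAD⁺+NADH), and the
creatine pool (Cr+PCr).

Reaction kinetics use four mechanism families:

- **One-step binding** (HK, PGI, PFK, PFK2, ALD, TPI, PGK, PGM, ENO, PK,
  CK): a reduced reversible law with lumped substrate and product binding
  terms, `χ·(Vf·S̃ − Vr·P̃)/(1 + S̃ + P̃)`. The allosteric multiplier χ is a
  product of saturable activator terms `[A]/([A]+K_A)` and inhibitor terms
  `K_I/([I]+K_I)`.
- **Random bi-bi** (LDH, PHGDH) and **random ter-bi** (GAPDH): NAD(H)
  oxidoreductases get the fuller denominators (each single-ligand term plus
  lumped forward/reverse terms); the reduced one-step form is numerically
  fragile for these steps. An ordered bi-bi variant of LDH is available
  (`ldh_mechanism = "ordered"`) and yields the same qualitative behavior —
  the ordered denominator simply drops the two non-cofactor single-ligand
  terms.
- **Transport**: facilitated (glucose, lactate, serine; symmetric
  carrier saturable in both compartments) and passive (oxygen; linear in
  the gradient).
- **Mass action**: adenylate kinase (2 ADP ⇌ ATP + AMP, Keq = 1), the
  ATPase load (first-order in ATP), and fructose-2,6-bisphosphatase
  (first-order in F26BP).

**Thermodynamic constraints.** Every reversible rate law is built through
the Haldane relation: `Keq = exp(−ΔG°/RT)` at T = 310.15 K, and
`Vrmax = Vfmax·Kmr/(Kmf·Keq)`. This reduces each reversible reaction to
three free parameters and guarantees — analytically, and asserted on random
states in the tests — that the net rate is zero exactly at equilibrium and
always points down the free-energy gradient.

A practical subtlety: concentrations are in mM but tabulated ΔG°′ values
assume a 1 M standard state. For reactions that change molecularity
(aldolase splits one molecule into two; GAPDH condenses three reactants
into two products) the equilibrium constant is not dimensionless in
concentration units, so the stored ΔG° values are re-referenced to a 1 mM
standard state (`ΔG°_mM = ΔG°_M − Δn·RT·ln 1000`). This is why the
parameter table lists aldolase at +2.7 kJ/mol and GAPDH at +24.1 kJ/mol:
the same physical equilibria, expressed on the scale the model computes
with. GAPDH's large positive value on this scale is the thermodynamic
strain that makes it a candidate bottleneck.

**Lumped compartments.** Oxidative phosphorylation is one reaction:
pyruvate + 3 O₂ (+ 12.5 ADP + 12.5 Pᵢ) → 12.5 ATP, Michaelis–Menten in
pyruvate, oxygen and phosphate, activated by ADP. The P/O-style yield of
12.5 ATP per pyruvate is configurable. The mitochondrial NADH shuttle
(malate–aspartate plus glycerol-3-phosphate, lumped) is a single saturable
capacity consuming cytosolic NADH. At any steady state its flux equals
`V_ox + 2·V_phgdh` by stoichiometry — the balance is an emergent identity,
checked in the tests, not an imposed constraint. Imposing it instantaneously
instead would freeze the linear combination BPG+3PG+2PG+PEP+PYR−NADH along
every trajectory: a spurious extra conservation law that makes steady states
non-isolated and forbids lower glycolysis from depleting under GAPDH
inhibition. The kinetic shuttle avoids both artifacts.

**Phosphate closure.** With no phosphate exchange, the network would
conserve total phosphate exactly — another spurious conservation law (the
documented structure has three). Real cells exchange Pᵢ with the medium
through Na/Pᵢ cotransporters; the model includes a linear Pᵢ exchange
(`PIT`) against an implicit fixed media phosphate (5 mM, an RPMI-like
value). A side effect worth knowing: at steady state the net Pᵢ exchange is
zero, so intracellular Pᵢ equals media Pᵢ in every converged realization.

## Parameters

The default parameter set is a curated, literature-plausible
reconstruction — no published per-reaction supplement is reproduced.
Michaelis constants are typical reported mammalian values (e.g. GLUT-like
glucose transport Km 1.5 mM, LDH Km for pyruvate 0.3 mM and for NADH 2 µM);
ΔG°′ values are textbook glycolysis numbers re-referenced as above;
conserved pools are physiological (adenylates 3.33 mM, NAD(H) 0.505 mM,
creatine 10.5 mM); media composition is culture-like (5 mM glucose, 1 mM
lactate, 0.2 mM O₂, 0.3 mM serine).

Maximal capacities were calibrated once, with three deliberate structural
choices, and then frozen:

1. **ATP demand controls the pathway.** The ATPase load (3.2/hr) is the
   dominant positive controller of lactate flux at baseline — the classic
   demand-driven picture of glycolysis.
2. **Overflow at the shuttle.** The NADH shuttle capacity (2 mM/hr) is
   only ~1.5× the baseline shuttle flux. When sampled realizations run
   glycolysis fast, the shuttle saturates, pyruvate oxidation (tied to the
   shuttle by the steady-state balance) cannot absorb the throughput, and
   the excess is fermented — an overflow mechanism that links high
   glycolytic rate to the Warburg phenotype.
3. **GAPDH is the lean step.** Every glycolytic enzyme except GAPDH has
   clear excess capacity; GAPDH (6 mM/hr, a few-fold above baseline flux)
   is both thermodynamically strained and kinetically lean, so it is the
   step whose expression level recurrently gates throughput across the
   ensemble — upper-glycolysis intermediates (most prominently FBP)
   accumulate behind it in high-flux states.

The baseline steady state under these defaults: ATP ≈ 3.2 mM, FBP ≈ 0.6 mM
(the low-FBP state), W ≈ 1.5. The ensemble statistics that the tests assert
(ATP density mode ≈ 3 mM; lactate fractions exceeding 95%; bimodal FBP and
ATP/ADP distributions; GAPDH as the top positive Warburg-correlate among
glycolytic enzymes) are properties of this frozen calibration, recomputed
from scratch by the test suite and the acceptance script — not numbers
stored anywhere in the package.

## The ensemble

Enzyme activities are sampled by Latin hypercube: for each sampled capacity
the interval from 10× below to 10× above baseline is divided into n equal
log-width strata, one uniform draw is placed in each, and the strata are
permuted independently per parameter. Log-uniform stratification is the
package default (a literal linear-uniform mode is available): over a
100-fold range, linear-uniform sampling concentrates 90% of draws in the
top decade, which under-explores low-expression regimes. Seventeen
capacities are sampled by default — the ten glycolytic enzymes, glucose and
lactate transport, PFK2, PHGDH, OxPhos, and the ATPase load.

Each draw is solved to steady state and passed through five feasibility
predicates: convergence; positivity (and a 100 mM physical cap — runaway
states, e.g. FBP equilibria beyond any physiological range, are rejected
rather than truncated); positive net glucose uptake; thermodynamic sign
consistency of every reversible flux; and local stability (no reduced-
Jacobian eigenvalue with real part above 1e-6). Rejections are kept in the
table with their reasons, so acceptance statistics are reportable.
Realizations that import and oxidize media lactate (negative net LDH flux)
can pass the filter; they carry `W < 0` and an undefined lactate fraction
and simply do not contribute to the fermentation-side statistics.

## Control analysis

Flux control coefficients are computed by finite differences on the log
scale: the capacity is rescaled by `exp(±δ)` (δ = 0.01 by default; one-sided
differencing is available), the steady state is re-solved, and
`Δln J_lac/Δln E` is returned. Two numerical choices matter:

- **Re-solves are Newton-only continuations** warm-started from the
  unperturbed root. The model is bistable in parts of activity space (the
  low/high FBP states); an integrator restarted from a perturbed parameter
  set can relax to the *other* branch, which would corrupt the derivative
  estimate catastrophically. Newton continuation stays on the perturbed
  root connected to the unperturbed one; if Newton fails the coefficient is
  reported missing, never fabricated.
- **Signed flux and step-size refinement.** Accepted realizations that
  net-import lactate carry a negative `J_lac`; there the log difference is
  replaced by the equivalent normalized linear difference
  `(J⁺ − J⁻)/(2δ·J₀)`, the same derivative extended to signed flux. Near
  `J_lac ≈ 0` the log response is strongly curved, so the ensemble-level
  control analysis refines the step size (δ/4, then δ/16) for any
  realization whose summation diagnostic drifts beyond 0.04 — a smaller
  step for the same estimator, not a different definition.
- **The summation theorem is a computable gate.** Every flux law is
  first-order homogeneous in the full set of capacities, so scaling all 24
  controllable steps by λ leaves every concentration fixed and scales every
  flux by λ — hence ΣFCC = 1 exactly. The tests verify the homogeneity
  directly and require |ΣFCC − 1| ≤ 0.05 on every accepted realization of a
  200-draw ensemble.

Correlation maps (FCC×FCC, FCC×metabolite) use Pearson or Spearman
correlations over accepted realizations with pairwise-complete handling of
missing coefficients, ordered by average-linkage hierarchical clustering on
1−correlation distance; ordering is deterministic with ties resolved by
label order.

## Warburg statistics

`W = J_lac/J_ox` and the lactate fraction `W/(1+W)` quantify the
fermentative split. The FBP state split defaults to a fixed 1 mM threshold —
between the high-micromolar low state and the millimolar high state — with a
deterministic two-cluster split on log concentration as the alternative
(`two_component_split`; k-means initialized at the extremes, labels by
cluster mean, fallback to the threshold when values are degenerate).
Pearson correlations are used for the Warburg panels and Spearman for the
state-conditioned flux–metabolite panels and the clustered maps. Density
summaries are deterministic equal-width histograms; the mode is the
midpoint of the highest-density bin (lowest bin on ties), and the
bimodality flag requires a two-cluster split in which both clusters hold at
least 5% of the mass and the density dips below 75% of the smaller peak
between the cluster centers.

## Tracer pipeline

The experimental-side module mirrors a ¹³C-glucose labeling experiment:
media sampled at 30/60/90/120 min, labeled lactate fitted by ordinary least
squares, the slope taken as the glucose-to-lactate flux, and R² > 0.98 as
the linearity gate. Fraction inhibited is single-site reversible occupancy
`dose/(dose + Ki)` — the simplest defensible mapping when only Ki values
are known. Empirical flux control coefficients are the least-squares slope
of ln(flux) against ln(residual activity), restricted by default to
residual activity ≥ 0.5: the FCC is a local derivative, and fitting deep
inhibition would conflate it with global dose–response curvature; if fewer
than three points fall in the window the full panel is used with a warning.

## Synthetic data

The generators stand in for the study's raw measurements:

- **Perturbation panels**: three inhibitors targeting PFK2, GAPDH and LDH
  (occupancy-scaled capacities), four log-spaced doses each spanning
  residual activity ~0.9–0.2, two vehicle conditions, three replicates — 14
  conditions, 42 experiments. Metabolite levels and lactate flux carry
  multiplicative log-normal noise (σ = 0.1), matching the relative-error
  structure of LC-MS intensities.
- **Tracer time courses**: linear accumulation plus additive Gaussian
  noise.
- **Dose–response panels**: noise-free steady-state re-solves across
  residual-activity levels, used to cross-validate the empirical against
  the analytic control coefficients.

What the generators do *not* emulate: instrument artifacts, isotopologue
distributions and natural-abundance corrections, peak-picking errors,
cell-to-cell heterogeneity, or biological branch pathways outside the model
(glycogen, pentose phosphate, alanine). Passing tests therefore demonstrate
internal consistency of the pipeline and the model's qualitative control
structure — not agreement with any particular cell line's measurements.

## Numerics

Steady states: stiff integration (`deSolve::lsoda`, rtol 1e-7, atol 1e-9)
in geometrically growing time chunks up to 1e4 model-hours, with a
relative-derivative convergence criterion `max |dC/dt|/max(C, 1e-9 mM)
≤ 1e-6` per hour, followed by damped-Newton polishing on the
conservation-reduced system (the three pool species eliminated) so that
residuals reach machine scale — necessary for the 1% finite differences of
the control analysis to be meaningful. Trajectories that orbit an unstable
fixed point (glycolytic oscillations) are detected by polishing to the
interior root and checking its stability; they are reported as
non-converged rather than consuming the full time horizon. All rate-law
denominators have the form 1 + nonnegative terms, so all-zero states yield
zero rates, never division errors; the integrator's transient small
negatives are floored at zero inside flux evaluation only, which cannot
break the conservation laws.

Problem sizes in the shipped tests were chosen to exercise the study design
at laptop scale: 500 draws for the ensemble-calibration statistics, 200
draws for the per-realization summation gate, 200 seeded replicates for the
tracer unbiasedness check. The generators accept larger n for
production-scale runs (the study design itself contemplates thousands of
draws).

## Known limitations

- The default parameter set is a reconstruction; absolute fluxes and
  concentrations are calibrated to plausible ranges, not fitted to data.
- Pyruvate oxidation is a single lumped reaction; mitochondrial redox is
  not resolved beyond the shuttle capacity, and the steady-state tie
  between shuttle and oxidation flux is a structural property of that
  lumping.
- Intracellular Pᵢ is pinned to the media value at steady state by the
  linear phosphate exchange.
- pH, ion balance, compartment volumes beyond one cytosolic pool, and the
  glycogen/pentose-phosphate/alanine branches are out of scope.
- FCCs are finite-difference estimates; coefficients far from the linear
  regime (|FCC| of several units near fold bifurcations) carry relative
  errors on the order of a percent, and the 0.05 summation gate reflects
  that.
- Under strong GAPDH inhibition the model either develops slow relaxation
  oscillations (recorded as non-converged, hence missing panel conditions)
  or relaxes to extreme FBP accumulations far beyond physiological
  concentrations: nothing in the model caps upper-glycolysis mass (no
  osmotic or solubility constraint), so only the thermodynamic
  back-pressure of PFK terminates the build-up. The ensemble's 100 mM
  feasibility cap rejects such states; the perturbation-panel generator
  reports them as simulated, to keep the inhibitor signature visible.
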