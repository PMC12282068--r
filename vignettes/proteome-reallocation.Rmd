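---
title: "Minimal proteome reallocation in enzyme-constrained dynamic FBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal proteome reallocation in enzyme-constrained dynamic FBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morp)
```

## The model

An enzyme-constrained (GECKO-style) metabolic model augments a
stoichiometric network `S·v = 0` with one pseudo-metabolite per enzyme,
one *usage* reaction per enzyme, and a protein pool:

* a catalyzed reaction `j` consumes `1/kcat_ij` of enzyme
  pseudo-metabolite `i` per unit flux, so at steady state the usage
  flux satisfies `e_i = Σ_j v_j / kcat_ij`, i.e. `v_j ≤ kcat_ij · e_i`;
* usage reaction `i` draws `MW_i` grams of pool per mmol of enzyme;
* the pool exchange is bounded above by the condition-dependent
  capacity `P` (g protein / gDW).

Units are fixed package-wide: fluxes and enzyme usage in mmol/gDW/h,
molecular weights in g/mmol, the pool in g/gDW, concentrations in g/L,
biomass in gDW/L. `build_ec_model()` performs the conversion; reversible
catalyzed reactions are split into irreversible `__fwd`/`__rev` pairs
(re-summed by `collapse_fluxes()` for reporting), and isozymes become
parallel arms by default (`isozyme_policy = "fastest"` keeps only the
highest-kcat copy; the field's converters do not agree on a single
policy, so both are exposed). Enzyme complexes are represented as one
pseudo-enzyme with a summed molecular weight — subunit stoichiometry is
not modeled. The pool capacity has no universal default and is a
required user input.

## Objectives

`fba()` maximizes a chosen reaction (growth, lactate export, NGAM — the
ATP-maintenance reaction id is always named explicitly, never
inferred). Because alternate optima are common, a second lexicographic
stage (on by default) fixes the optimal objective value and minimizes
total enzyme usage; this makes solutions deterministic, which matters
when they become MORP references.

`morp()` minimizes the L1 distance between the model's enzyme-usage
vector and a reference usage vector, subject to the same constraints.
The absolute values are linearized exactly, not heuristically; the
default formulation introduces one auxiliary variable `d_i` with
`d_i ≥ ±(e_i − ref_i)` and minimizes `Σ d_i`. A second, independent
formulation (`linearization = "split"`, `e_i = ref_i + p_i − q_i` with
`p, q ≥ 0`) is kept and the test suite asserts both agree to 1e-8 —
a standing cross-check on the encoding. MORP adds no growth or
maintenance floor beyond the model's own bounds: whether the organism
must keep growing during a perturbation is a biological claim the
bounds should express, not the objective.

MORP minimizes usage in the model's native mmol/gDW/h, not
mass-weighted grams: the distance is a sum over usage *fluxes*, and the
mmol scale is what the usage reactions carry. A mass-weighted variant
is a one-line change (scale the reference and usage columns by MW) and
deliberately not a separate code path.

`min_total_proteome()` fixes measured exchange fluxes and minimizes the
pool draw — the most enzyme-efficient state consistent with observed
exchange rates.

## Dynamics

`simulate_dfba()` implements dFBA by the static optimization approach:
the horizon is cut into intervals of width `dt` (default 0.1 h); each
interval solves a static LP whose sugar-uptake bounds come from Monod
kinetics evaluated at the previous interval's concentrations; then
biomass and concentrations advance by explicit Euler,
`X ← X(1 + µ·dt)`, `C ← C + v_ex · MW · X · dt`. Two numerical guards:
uptake is additionally capped at `C/(MW·X·dt)` so one Euler step can
never drive a concentration negative, and sub-1e-9 negative residues
are clamped to zero (anything larger raises a step-size error).

The uptake constraint is an *equality* by default, as the recursion is
written with `v_s,k` equal to the Monod value; `uptake_bound = "upper"`
relaxes it to an upper bound, which is needed when extra constraints
(e.g. a blocked branch) make the full Monod uptake infeasible — the
homolactic-yield test in the suite is exactly such a case.

Phases (`phase()`) pair an objective with a switch condition (species
falling to a threshold, or a fixed time) and optional phase-local
bounds. In a dMORP phase, each interval's reference is the previous
interval's enzyme usage; the first MORP interval inherits the last
solution of the preceding phase. Biomass decline after substrate
exhaustion (a lag-phase phenomenon) is not modeled mechanistically;
trajectories simply stop growing.

## The synthetic organism

`make_toy_ccm()` builds a deliberately small lactic-acid-bacterium
central-carbon model: glucose and trehalose transport (one trehalose →
two hexose-phosphates), lumped EMP glycolysis, lactate dehydrogenase, a
phosphoketolase branch splitting hexose-phosphate into pyruvate +
acetyl-phosphate + CO₂ (acetyl-phosphate goes to acetate via acetate
kinase, ATP-yielding, or to ethanol, NADH-consuming), an acetoin
branch, a lumped biomass drain (6.5 mmol hexose-phosphate and 30 mmol
ATP per gDW — about 39 mmol carbon/gDW, a realistic cell carbon
content), and an NGAM floor of 1 mmol ATP/gDW/h. Carbon is exactly
balanced (asserted by `check_mass_balance()`); ATP/NAD bookkeeping is
lumped but internally consistent (EMP nets 2 ATP and 2 NADH per hexose
after transport, the phosphoketolase route nets less ATP), so the
classical yield structure emerges: homolactic 1 g/g, heterolactic
0.526 g/g on trehalose.

What the generator emulates: hierarchical sugar utilization, overflow
between a high-ATP-yield/pool-expensive route and a
low-yield/pool-cheap route, and the resulting fermentation-mode switch.
What it does not: realistic kinetic parameters of any particular
organism, amino-acid metabolism, genome scale (8 lumped enzymes vs
hundreds), pH chemistry, or lag-phase physiology. Tests passing on this
model demonstrate the *algorithms* behave as specified under conditions
engineered to exhibit the phenomenon — they say nothing about parameter
fits to real fermentations.

### Calibration

The qualitative target is twofold: (a) growth maximization at fast
glucose uptake must be homolactic-dominant, and (b) dMORP after the
switch must route a materially larger flux share through
phosphoketolase. Three parameter relations deliver this, chosen once
and frozen as the defaults:

* the distal EMP lump is pool-expensive (MW/kcat = 0.20/60) while the
  PK branch is pool-cheap (0.02/40), so at the glucose-phase uptake
  (v_max 10 mmol/gDW/h, Km 0.05 g/L — hexose transporters saturate at
  tens of mg/L) the pool capacity of 0.024 g/gDW binds and ~25% of the
  flux overflows through PK even though EMP yields more ATP;
* the PK kcat (40/h) is *lower* than the EMP kcat (60/h) per lumped
  step, so per unit flux PK retains more usage; when the trehalose
  phase opens at a much lower uptake (v_max 1 mmol/gDW/h, Km 1 g/L —
  disaccharide transport is slower and weaker-affinity), the
  reallocation objective prefers to keep the PK enzymes busy up to
  their reference usage, and the phase goes fully heterolactic;
* the packaged schedule switches phases when glucose falls below
  1 g/L. This threshold sits above the per-interval Euler consumption
  (~0.7 g/L at peak biomass): the dMORP reference is then the
  high-flux late-glucose state. A threshold below that would make the
  reference a final sliver interval whose uptake is dominated by the
  availability cap — a discretization artifact, not a biological
  state. The leftover ≤1 g/L of glucose is consumed in the first
  couple of dMORP intervals.

`make_toy_ccm()` re-checks properties (a) and (b) on construction and
aborts with a configuration error if a user-supplied parameter set
breaks them — a miscalibrated generator must fail loudly, not return a
fixture that silently cannot show the transition.

## Sampling

`sample_flux_space()` runs hit-and-run on the polytope
`{v : S·v = 0, lb ≤ v ≤ ub}`: directions are drawn isotropically in the
null space of `S` (a full SVD basis), so proposals never leave the
stoichiometric subspace, and the chord through the current point is
intersected with the FVA box. Coordinates with zero FVA width are
frozen — this doubles as the degenerate-polytope fallback (a fully
fixed polytope returns its unique point with a warning). The walk
starts from the mean of the FVA optimizer vertices, burns in
`100 × dim` steps and records every `thinning = 100` steps by default;
a fixed seed reproduces the walk bit-exactly, and a longer run with
the same seed extends rather than replaces it. No exact-uniformity
guarantee is claimed; containment comparisons against it are
qualitative by design.

## Numerical core

No linear-programming package is declared as a dependency; the solver
is a dense bounded-variable two-phase primal simplex (`lp_solve()`),
with Bland's rule engaged after runs of degenerate pivots, feasibility
and optimality tolerances of 1e-9, and genuine unboundedness detected
by re-solving with relaxed clamps on infinite bounds. It is validated
in the test suite against exhaustive vertex enumeration on random
bounded LPs and against an unrelated simplex implementation
(`pracma::linprog`) on the problem form that implementation supports.
The models this package targets are small (tens to a few hundred
columns); a dense simplex is the right tool at that scale and keeps
the package self-contained.

## Problem sizes in the packaged runs

The packaged scenario integrates 140 intervals (14 h at dt 0.1 h) over
a 26-reaction enzyme-constrained network; the dt-robustness check
repeats it at dt 0.05 h and asserts phase-end concentrations move by
<2%. The sampler checks draw 1,000 samples at thinning 20 on the same
network. The MORP oracle comparisons use two-route models whose usage
vector is affine in two free fluxes, so the brute-force optimum is a
four-round multiscale grid search — convex piecewise-linear objectives
make that oracle exact to ~1e-8 of the box scale.

## Known limitations

* The simplex is dense; genome-scale models (thousands of reactions)
  would need a sparse LP backend behind the same `lp_solve()` contract.
* Catabolite repression is imposed as a phase bound, not derived from
  regulation.
* Measured-bounds injection interpolates exchange bounds linearly in
  time; deriving rate bounds from concentration measurements (finite
  differences, smoothing) is left to the caller.
* `rmse_products()` pools squared errors across products by default;
  per-product averaging is available (`mode = "per_product"`) since
  published RMSE figures rarely state the pooling convention.

## A note on shape

Model containers are plain S3 records (a metabolic network is a graph
with bounds, not a samples-by-variables table); everything a user
analyses — solutions, trajectories, samples, yield and fold-change
reports — is a tibble or carries `tidy()`/`glance()`/`autoplot()`
methods, so results flow directly into dplyr/ggplot2 pipelines.
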