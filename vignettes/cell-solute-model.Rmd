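---
title: "The cell–solute well model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cell–solute well model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellsolute)
```

This vignette documents the model, the numerical scheme, the screening and
calibration machinery, and the design decisions taken where more than one
reasonable choice existed. Everything quantitative shown here is computed by
the code at build time or asserted by the package's test suite; nothing is
quoted from elsewhere.

## The model and its assumptions

The package describes a cylindrical culture well containing a thin
cell-seeded collagen gel (plastic-compressed, so cells are concentrated
roughly 40-fold relative to seeding) under a column of culture medium.
Four state variables evolve on the axial coordinate: oxygen `c`, glucose
`s`, VEGF `v` (all kg/m³) and viable cell density `n` (cell/m³, gel only).

Key modelling assumptions:

- **One spatial dimension.** The well is axisymmetric and its wall slope is
  negligible, so radial variation is dropped entirely. Fields vary only with
  depth.
- **Death-only cell kinetics.** The cell line is conditionally immortalised
  and does not proliferate under the culture conditions modelled, and
  migration in collagen is negligible on a 24-h timescale. `n` therefore
  only decreases, at a rate with a baseline component `delta_0` and
  saturating hypoxic (`delta_c`) and glucose-deprivation (`delta_s`)
  components that switch on below the respective half-saturation scales.
- **Michaelis–Menten consumption.** Oxygen uptake saturates with
  half-saturation `c_half`; glucose uptake likewise (`s_half`), times an
  anaerobic enhancement `1 + A*c_half/(c + c_half)` that interpolates from 1
  (oxygen-replete) to `1 + A` (anoxic) on the same oxygen scale at which
  aerobic metabolism weakens — one new parameter buys the Pasteur-like shift
  to glycolysis.
- **VEGF secretion** has an oxygen-proportional baseline `alpha*c` and a
  hypoxia-gated term `beta*exp(-c/c_tau)`, and the per-cell rate is divided
  by `1 + n/n_tau` so that crowding halves it at `n = n_tau`. The typeset
  form of this production term is ambiguous in its source; the reading
  implemented here, `G = n*(alpha*c + beta*exp(-c/c_tau))/(1 + n/n_tau)`,
  is the only one in which `n_tau` acts as a crowding factor and `alpha`,
  `beta` carry their published units. This choice is deliberate and
  documented rather than silent.
- **`n_max` enters no equation.** With proliferation fixed at zero the
  maximal cell density is metadata; it is carried on `parameter_set` objects
  for completeness only. Excluding it, enumerating the free constants of the
  governing equations gives exactly 19 parameters.

## Units

Internally everything runs in modeling units (kg/m³, cell/m³, m, s);
percent O₂, mmHg, mol/mL, mM, pg/mL and cells/mL exist only at the I/O
boundary (`convert_oxygen()`, `convert_glucose()`, `convert_vegf()`).
The oxygen scale is tied together by one solubility constant:
1% O₂ ≡ 7.6 mmHg ≡ 1.33×10⁻⁸ mol/mL ≡ 4.256×10⁻⁴ kg/m³ (O₂ at 32 g/mol).
This reproduces the published dual listing of the oxygen half-saturation
(1.65×10⁻⁸ mol/mL ↔ 1.24 % O₂) to three figures; the published kg/m³ value
(5.13×10⁻⁴) is about 3% below what any single solubility constant would give
from the mol/mL value. The kg/m³ (modeling-unit) values are taken as
authoritative, and the mismatch is recorded here rather than absorbed.

Similarly, four of the packaged best-fit constants lie outside the
literature intervals of `parameter_bounds()` — `D_c_gel`, `D_s_gel`,
`D_s_med` and `M_s`:

```{r}
validate_parameters(default_parameters())
```

`D_s_med` below the gel value is particularly suspect (a likely transcription
slip in its source), but the fixture reproduces the published values
verbatim. Because of these excursions, the default *calibration* intervals
(`calibration_bounds()`) are the literature intervals enlarged just enough to
cover the published fit (hull with ⅓×–3× the fixture value); Morris screening
uses the strict literature intervals.

## Geometry defaults

The published description fixes the cast gel volume (240 µL) and the seeding
densities, but not the post-compression thickness or the medium volume. The
package's defaults are: well radius 3.175 mm (96-well), compression factor
40 (the ratio of post-stabilisation to seeded density, e.g. 0.5→20 ×10⁶
cells/mL), giving a 6 µL, ≈0.19 mm gel; and 200 µL ≈ 6.3 mm of medium, the
volume the staining protocols use. All are arguments of `well_geometry()`.

## Numerics

`simulate_well()` integrates the coupled system with a cell-centred finite
volume discretisation on a two-part mesh: by default 100 cells, 20% uniform
in the gel and 80% uniform in the medium, with the gel–medium interface
exactly on a cell face and interface fluxes from the harmonic mean of the
two half-cell resistances (this is what makes the flux continuous across the
material discontinuity).

Time integration is backward-Euler for diffusion with reactions linearised
about the state at the start of each step: consumption and degradation terms
enter the implicit matrix diagonal as `k*x` with `k` frozen at the current
state, and the death ODE is solved pointwise as
`n/(1 + dt*delta)`. The resulting tridiagonal systems are M-matrices, so the
scheme is unconditionally stable and positivity-preserving at any `dt`; an
explicit scheme would be unstable at `dt = 100` s on ~10 µm gel cells, which
is why the default is semi-implicit. Values in `[-1e-12, 0)` arising from
roundoff are clipped to zero; any larger undershoot raises an error rather
than being hidden.

Default resolution is 100 cells and `dt = 100` s. Doubling both changes the
24-h gel-average oxygen by well under 1% (the acceptance script recomputes
this number), and the test suite checks that the observable converges
monotonically under successive refinement. Tests that run hundreds of
forward solves (calibration, screening) use a reduced 50-cell,
`dt = 300` s configuration; at that resolution the same qualitative
behaviour holds and a 24-h solve takes ~10 ms.

Initial conditions: gel oxygen at the 12% preconditioning level, medium
oxygen at ambient, glucose 25 mM (medium) and 1.25 mM (gel), zero VEGF,
uniform `n0` in the gel. The probe observable is the gel-centre
(axial midpoint) oxygen by linear interpolation of cell-centre values —
"centre of the construct" could also mean the interface region, but the
midpoint reading is adopted and used consistently for synthetic data and
calibration. The medium is not refreshed during the simulated 24 h.

## Morris screening

`morris_design()` builds classic one-at-a-time trajectories on a four-level
grid (`delta = 2/3`) and selects, from a 500-candidate pool, the `r = 40`
most mutually spread trajectories by a greedy maximin on the summed pairwise
trajectory distance. Parameters whose interval spans at least two decades
are sampled in log₁₀ space — a uniform linear sample of an interval like
`[3.2e-20, 2.5e-17]` would almost never visit the lower decades.
`morris_statistics()` reports `mu_star` (mean |EE|, overall influence) and
`sigma` (EE standard deviation with divisor r, matching the screening
formula as printed in its source, rather than the n−1 sample form) plus the
`sigma/mu_star` classification. The screening outputs are the four 24-h
gel averages at the reference condition (1% ambient, 60×10⁶ cells/mL);
the reference condition is configurable since the original screening
condition is not stated.

## Particle-swarm calibration

`pso_minimize()` is a standard global-best swarm: inertia `w`, cognitive
`c1`, social `c2`, fresh uniform multipliers per coordinate, Latin-hypercube
start at rest, velocities clamped to half the range, bounds handled by
clipping with velocity zeroing. Wide-ranged coordinates are searched in
log₁₀ space under the same two-decade rule as the screening. Each iteration
evaluates every particle once, so 20 particles × 1250 iterations is exactly
25,000 forward evaluations; the optional stall-based early stop (quit after
`stall_iters` iterations with relative improvement below `stall_tol`) is off
by default so that budget is exact.

The L1 cost (`calibration_cost()`) averages |prediction − observation| per
species on nondimensionalised values — oxygen by the condition's ambient
concentration, glucose by the initial 25 mM, cells as viable fractions —
and sums over species. VEGF starts at zero, where "normalise by the initial
concentration" is undefined; its block is normalised by the maximum observed
value instead. One forward run per unique (ambient, density) condition
serves all species within a cost evaluation (12 runs cover the full design).

`calibrate_two_step()` mirrors the two-stage structure of the original
procedure: the VEGF field does not feed back on oxygen, glucose or cells, so
the ten non-VEGF constants are fitted first (`w = 0.6`) against the oxygen
traces, glucose and viability blocks, and the six VEGF constants afterwards
(`w = 0.7`) with step 1 frozen. The medium diffusivities and `n_max` stay
fixed throughout, as the screening identifies them as nominal-value
parameters. The three observation blocks in step 1 are weighted only by
their 1/Ω factors, with no additional inter-block weights.
`calibration_spread()` repeats the fit under several seeds and reports
per-parameter min/median/max — swarm optima should be quoted with that
spread, not as point values.

## Synthetic data

`generate_dataset()` emulates the experimental measurement structure: probe
oxygen traces (mmHg, half-hourly for 24 h) at 1/3/7% ambient for the highest
density only (144 observations), and 24-h endpoint glucose (mM, medium),
viable fraction, and VEGF (pg/mL, medium) on the 4 × 3 ambient-by-density
grid (12 each). The "normoxic" level is labelled 19% following the run
matrix of the original design (its experimental table says 21%; the
discrepancy is noted, and either value can be passed). Noise is
multiplicative Gaussian truncated at zero with per-block CVs defaulting to
5% (oxygen, glucose) and 8% (viability, VEGF) — error bars in the source are
graphical only, so these are conservative, configurable choices. Viable
fractions are additionally capped at 1. Provenance (true parameters, design,
noise, seed) is recorded so `regenerate_dataset()` reproduces a dataset
bit-identically.

What the generator does *not* emulate: the nested replicate structure of
real experiments (independent repeats × samples are collapsed into i.i.d.
noise), assay chemistry, probe drift, or imaging artifacts. Passing recovery
tests on these pseudo-experiments therefore demonstrates that the inverse
machinery works when the model is correct — it does not validate the model
against biology.

## Degenerate inputs and edge behaviour

- `n0 = 0` (acellular) runs are legal and used for equilibration checks.
- A dataset with only VEGF observations skips calibration step 1 with an
  explicit warning and requires the non-VEGF constants to be supplied.
- A `t_end` that is not a multiple of `dt` is handled by one shortened final
  step, with a message.
- Forward-model failure inside a cost evaluation yields `+Inf` (the swarm
  simply avoids that region); failure at every initial particle is an error.

## Known limitations

- The solver is 1D: no radial gradients, advection, gel swelling or
  temperature dependence.
- The death law is memoryless; transient hypoxia leaves no history effect.
- `delta_0` and `delta_c` trade off along a ridge when only low-oxygen
  conditions are observed; the 19%-ambient viability observations are what
  separates them, so sparse or noisy normoxic data widen the recovered
  spread of both.
- At 5% measurement noise the glucose-side constants (`M_s`, `s_half`, `A`,
  `D_s_gel`) are weakly identified from 24-h endpoint data alone. The
  oxygen-side constants (`M_c`, `c_half`, `delta_0`) are identifiable in
  principle — a local refinement started at the truth stays within a few
  tens of percent of it — but the step-1 cost surface has neighbouring local
  basins only a few percent apart in cost, in which `c_half` and `D_c_gel`
  trade off against each other. Heavily scaled-down swarm budgets (hundreds
  to a few thousand forward evaluations) can settle in such a neighbouring
  basin; recovered values should therefore always be quoted with their
  multi-seed spread (`calibration_spread()`), and tight single-run recovery
  should only be expected at full swarm budgets.
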