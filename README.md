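# cellsolute

Reaction–diffusion modelling of oxygen, glucose, VEGF and viable-cell density
in plastic-compressed, cell-seeded collagen gels cultured in multiwell plates.

## The problem

Therapeutic cells embedded in engineered constructs (for example nerve repair
constructs bridging a peripheral nerve gap) experience steep nutrient
gradients: oxygen arrives only from the medium–air interface, glucose from the
culture medium, and the cells' own metabolism depletes both while hypoxia
drives VEGF secretion. `cellsolute` implements a two-domain, one-dimensional
finite-volume model of this system, together with the tools needed to
parameterise it: Morris elementary-effects screening of all model constants
and a two-step particle-swarm calibration against the four kinds of
measurement such experiments produce. A synthetic pseudo-experiment generator
makes the whole calibration loop testable without external data.

## The model

On the axial coordinate of a culture well (gel of height ~0.19 mm below a
~6.3 mm medium column), with oxygen c, glucose s, VEGF v (kg/m³) and viable
cell density n (cell/m³):

- **Oxygen** — diffusion with Michaelis–Menten consumption in the gel:
  ∂c/∂t = D∇²c − M_c·n·c/(c + c̄)
- **Glucose** — diffusion with consumption enhanced up to (1 + A)-fold under
  anoxia: ∂s/∂t = D∇²s − M_s·n·s/(s + s̄)·(1 + A·c̄/(c + c̄))
- **VEGF** — diffusion, first-order degradation K, and crowding-saturated,
  hypoxia-gated secretion: G = n·(α·c + β·e^(−c/cτ))/(1 + n/nτ)
- **Cells** — death-only kinetics:
  ∂n/∂t = −n·(δ₀ + δc·c̄/(c + c̄) + δs·s̄/(s + s̄))

Oxygen is held at the ambient set-point at the medium–air interface; all
other outer boundaries are zero-flux; concentration and flux are continuous
at the gel–medium interface. Counting every constant above over both domains
gives 19 free parameters.

## Worked example

```r
library(cellsolute)
p <- default_parameters()          # the packaged calibrated constants
sim <- simulate_well(p, ambient_o2 = 1, n0 = 60e6)
print(sim)
#> Well simulation: ambient 1% O2, n0 = 6e+07 cells/mL, 24 h
#>   mesh: 100 cells (20 gel), dt = 100 s
#>   24-h gel averages: O2 1.348e-04 kg/m3 (2.41 mmHg), glucose 15.4 mM
#>   viable fraction: 0.628
#>   medium VEGF: 969 pg/mL
```

After 24 h at 1% ambient oxygen and 60×10⁶ cells/mL, the gel interior sits at
about 2.4 mmHg (the cells have pulled the centre far below the 7.6 mmHg
ambient), about 63% of the seeded cells remain viable, and roughly
970 pg/mL of VEGF has accumulated in the medium — the hypoxic secretion gate
is wide open at this oxygen level. An acellular run
(`generate_acellular_trace(1)`) instead relaxes from the 12% preconditioning
level to ambient within a few hours, confirming that the depletion above is
metabolic, not diffusive.

Sensitivity screening and calibration:

```r
scr <- morris_screen(r = 40, seed = 1)        # mu*, sigma per output
ds  <- generate_dataset(seed = 1)             # synthetic pseudo-experiment
fit <- calibrate_two_step(ds,
         config1 = swarm_config(20, 1250, w = 0.6, seed = 1),
         config2 = swarm_config(20, 1250, w = 0.7, seed = 2))
```

A command-line wrapper with `simulate | morris | calibrate | synth | recover`
subcommands is installed at
`system.file("cli", "cellsolute.R", package = "cellsolute")`.

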