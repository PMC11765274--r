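# intertrack

Monte Carlo simulation of **intertrack recombination in water radiolysis**:
what happens to radical and molecular yields when two ion tracks arrive so
close in space and time — as at ultra-high (FLASH) dose rates — that their
chemistry overlaps before it homogenizes.

The package evolves pairs of track segments, separated by a transverse
distance Δx and an arrival delay Δt, through the heterogeneous chemical
stage (1 ps → 1 µs after the second track) with a compiled step-by-step
Brownian reaction–diffusion engine, and compares the yields against the
non-interacting (NI) two-track reference. It is aimed at radiation
chemists and radiobiology modellers exploring the spatiotemporal limits of
the intertrack hypothesis.

## Model in brief

* **Track surrogate** — energy-deposition events are a Poisson process
  along the beam axis with mean `LET × depth / E_event`; transverse
  offsets follow a Gaussian core (σ = 2 nm) plus a log-uniform
  delta-electron tail reaching 1 µm. A prechemical branching table
  dissociates each event into the seven tracked species
  (OH·, e⁻aq, H₃O⁺, H·, H₂, H₂O₂, OH⁻) at 1 ps.
* **Chemical stage** — Brownian displacements with per-axis sd √(2 D Δt);
  bimolecular reactions via Smoluchowski radii
  `R = k′ / (4π (Da + Db))` derived from literature rate constants, with a
  Brownian-bridge correction for pairs that cross the radius inside a
  step. The timestep grows 0.1 ps → 10 ps, one decade per decade of
  elapsed time.
* **Two-track scheduling** — the delayed track is created at 1 ps but
  frozen (invisible to counts and to the deposited energy `E(t)`) until
  the clock reaches Δt; activation resets the timestep and lets both
  populations react. Yields are G-values `G = N/E × 100` (molecules per
  100 eV) and the intertrack effect is the normalized 1-µs difference
  `ΔG = (G_pair − G_NI) / G_NI` with
  `G_NI = [G_NI(1 µs + Δt) + G_NI(1 µs)]/2`.

## Worked example

Two carbon-like track segments (LET 30 keV/µm, 0.25 µm depth) at Δx = 1 nm
and Δt = 1 ps, eight replicates, against a matching NI ensemble:

```r
library(intertrack)

p  <- particle_spec("carbon", energy = 40, let = 30, depth = 0.25)
ni <- lapply(1:8, function(r) run_ni(p, dt_delay = 1,
                                     seed = derive_seed(1, 500 + r, 2)))
cond <- run_condition(p, dx = 1, dt_delay = 1, replicates = 8,
                      seed = 1, ni_runs = ni)
print(cond$stats[, c("species", "g_pair", "g_ni", "delta_g", "se", "p")],
      digits = 2)
```

```
  species g_pair  g_ni delta_g    se       p
1      OH   0.54 0.696   -0.22 0.026 2.3e-06
2    e_aq   0.20 0.374   -0.46 0.028 3.2e-07
3    H3O+   0.40 0.627   -0.36 0.030 3.4e-07
4       H   0.20 0.230   -0.15 0.096 1.6e-01
5      H2   0.18 0.140    0.29 0.065 3.3e-04
6    H2O2   0.11 0.094    0.16 0.111 1.4e-01
7     OH-   0.20 0.253   -0.22 0.063 1.5e-02
```

Read: at minimal separation the primary radiolytic products are depleted
(OH· −22 %, e⁻aq −46 %, H₃O⁺ −36 % relative to NI — the pair behaves like
a single track of doubled local density), while the molecular products are
enhanced (H₂ +29 %, H₂O₂ +16 %); `se` is the replicate standard error of
ΔG and `p` the Welch t-test against the NI ensemble. Sweep `run_grid()` over the
Δx/Δt grids to build the full heatmap (`plot_delta_g_grid()`).

A command-line front end (`inst/exec/intertrack`) exposes `pair`, `ni`
and `grid` subcommands over the same functions, configured by flags or a
YAML file (see `default_config()` / `load_config()`).

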