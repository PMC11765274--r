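---
title: "Simulating intertrack recombination in water radiolysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating intertrack recombination in water radiolysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package addresses

At ultra-high (FLASH) dose rates, particle tracks arrive so close together
in space and time that the radicals they produce in water can react across
tracks before the chemistry has homogenized.  `intertrack` simulates pairs
of ion tracks separated by a transverse distance $\Delta x$ and an arrival
delay $\Delta t$ through the heterogeneous chemical stage (1 ps to 1 us
after the second track) and quantifies how intertrack recombination shifts
the radiolytic yields relative to two non-interacting (NI) tracks.

Yields are expressed as G-values,

$$G(t) = \frac{N(t)}{E(t)} \times 100,$$

molecules per 100 eV of deposited energy, where $E(t)$ is a step function:
only the first track's energy counts before the second arrives.  The
intertrack effect at a given $(\Delta x, \Delta t)$ is the normalized
difference read 1 us after the second arrival,

$$\Delta G_{\mu s} = \frac{G_{pair}(1\,\mu s + \Delta t) - G_{NI}}{G_{NI}},
\qquad
G_{NI} = \tfrac12\left[G_{NI}(1\,\mu s + \Delta t) + G_{NI}(1\,\mu s)\right],$$

the NI reference averaging the two chemical ages the pair's tracks have at
the readout instant.

## The three-stage model

**Physical and prechemical surrogate.**  Transporting electrons through
explicit cross-sections is out of scope; the package replaces the sub-ps
stages with a parametric surrogate.  Energy-deposition events are placed
along the beam axis (+z) over the scoring depth as a Poisson process with
mean `LET x depth / mean_event_energy`; each event carries
`mean_event_energy` (default 62.5 eV, i.e. 16 events per keV -- a tunable
surrogate parameter, not a measured W-value).  Transverse offsets come from
a two-component radial profile: a Gaussian core (`core_sd_nm = 2`)
representing ionizations close to the ion path, plus a log-uniform tail
(fraction 0.05, 5--1000 nm) standing in for the delta-electron penumbra, so
that a small fraction of species lies beyond 500 nm of the axis -- the
feature that lets tracks interact weakly even at micrometre separations.
Each event then dissociates by the prechemical branching table:
ionizations yield {OH, H3O+, e_aq}; excitations yield {OH, H} (p = 0.5),
{H2, 2 OH} (p = 0.15) or relax radical-free (p = 0.35); event classes are
ionization (0.72) and excitation (0.28).  These ratios are literature-style
placeholders -- published track-structure branching data are not reproduced
here -- and are fully configurable.  Products receive an isotropic Gaussian
displacement per channel (0.8 nm for heavy fragments; 4 nm for electron
thermalization).  The inventory is stamped at 1 ps.

**Chemical stage.**  From 1 ps the seven tracked species (OH, e_aq, H3O+,
H, H2, H2O2, OH-) undergo step-by-step Brownian dynamics: per step each
active molecule takes independent Gaussian increments with per-axis sd
$\sqrt{2 D \,\Delta t}$, then all reactive pairs are tested against their
channel's reaction radius.  Radii derive from measured rate constants via
the fully diffusion-controlled Smoluchowski closure
$R = k' / (4\pi(D_a + D_b))$ (1 M$^{-1}$s$^{-1}$ = 1.6606e-12 nm$^3$/ps);
no acceptance probabilities distinguish partially diffusion-controlled
channels.  The default reaction set is the nine-channel system closed over
the tracked species (electron recombinations with e_aq/OH/H/H3O+/H2O2,
OH+OH, OH+H, H+H, H3O+ + OH-), with rate constants from a standard
literature compilation; the OH + H2O2 channel is disabled to keep the
species set closed.  Solvent water is implicit: channels may emit or
consume it (e.g. e_aq + e_aq consumes two waters), and every emission is
logged so hydrogen, oxygen and charge balances close exactly -- a property
the test suite checks on full runs.

**Timestep schedule.**  The step grows from 0.1 ps to 10 ps, by default one
decade of dt per decade of elapsed time (0.1 ps below 1 ns, 1 ps below
10 ns, then 10 ps).  Only the endpoints of that range are externally
prescribed; the decade staircase is this package's choice.

## Multi-track scheduling

Both 1-ps inventories are sampled up front (the sub-ps stages of a delayed
track are independent of the first track), but the delayed track is frozen:
inactive molecules never move, never react, and contribute neither to
$N(t)$ nor to $E(t)$.  When the global clock reaches $\Delta t$ (clamped to
no earlier than 1 ps) the second track activates, the schedule clock resets
to `dt_min` to resolve the fresh track's fast kinetics, and $E(t)$ steps
up.  At the activation instant the combined G-value satisfies the counting
identity $G = (N_1(\Delta t) + N_2(1\,ps)) / (E_1 + E_2) \times 100$
exactly -- primary species peak, secondary species drop -- which the test
suite asserts to machine precision as a structural check of the
freeze/activate bookkeeping.

Replicate ensembles are normalized by energy: `replicate_count()` picks
`ceiling(target / (LET x depth))` with a 2 MeV default target.  One NI
ensemble (evolved past the largest delay of interest) can be shared across
all $(\Delta x, \Delta t)$ conditions because NI runs depend on neither.

## Numerical choices

* **Geminate recombination across a step.**  With a growing step, a pair
  can diffuse through its reaction radius between endpoint checks.  Pairs
  ending outside the radius therefore react with the standard
  Brownian-bridge probability
  $\exp[-(r_0 - R)(r_1 - R) / ((D_a + D_b)\,\Delta t)]$.  Without this
  correction the isolated-pair oracle (below) is biased low once dt reaches
  10 ps; with it the simulated ultimate reaction fraction reproduces the
  Smoluchowski closed form within Monte Carlo error.  The single-step
  `react()` surface keeps the plain endpoint criterion (`bridge = FALSE`)
  for transparent unit tests.
* **Pair resolution order.**  Candidate pairs are processed in increasing
  distance (ties broken by index), each molecule consumed at most once per
  step -- deterministic given positions.  Products are placed at the pair
  midpoint (optional Gaussian jitter, default 0) and react from the next
  step on.  Neither rule is externally prescribed; both are this package's
  choices.
* **Boundaries.**  Open by default: at 1 us the diffusion length
  (~0.2 um) is small against the 5 um transverse scale, and molecules are
  counted wherever they are.  A periodic cube is available for well-mixed
  kinetics checks.
* **Readout.**  $G(1\,\mu s + \Delta t)$ is read at the nearest logged time
  at or before the target (no interpolation); forced log points are placed
  at 1 ps, the activation time and the readout times.  The logging grid is
  log-spaced, 20 points per decade.
* **Identical-reactant channels** use the same radius closure as mixed
  pairs; no factor-of-two convention is applied to the rate constant.
* **Seeds.**  One global seed expands into independent per-replicate,
  per-track, per-phase streams via splitmix64 mixing (`derive_seed()`);
  derived seeds stay below $2^{31}$.  The engine RNG (xoshiro256++) is
  independent of R's global state.

## Statistical analysis

Per condition, `run_condition()` reads each replicate's G-values at
$1\,\mu s + \Delta t$, forms $\Delta G_{\mu s}$ from the ensemble means
with a delta-method standard error, and attaches a Welch two-sample t-test
p-value (pair vs NI replicates, unpaired) per species.  p-values are
reported raw -- no multiplicity correction, matching the study design this
package follows.  Where a scan must decide "no species significant", the
package's own pre-set threshold is alpha = 0.01 per species: with seven
species tested jointly and no correction, alpha = 0.05 per species would
produce family-wise false alarms in roughly a third of null conditions,
while 0.01 keeps that near 7% with ample power for the >10% effects at
close separations.  (The bundled acceptance script's micrometre scan keeps
the conventional alpha = 0.05 per species, the threshold its reported
bound is defined with.)

A t-test on identical or zero-variance samples is defined as p = 1 (equal
means) or p = 0; species absent from the NI reference get NA rather than
an infinite ratio.

## What the generator emulates -- and what it does not

The surrogate reproduces the *structure* that drives intertrack effects: a
dense core with realistic radical spacing, a weak far tail, Poisson event
statistics, and exact energy bookkeeping.  It does not reproduce absolute
published yields: with the default 62.5 eV per event the 1-ps G-values are
roughly a third of experimental water-radiolysis values, so intratrack
kinetics are correspondingly slower and secondary-product inventories
smaller than in cross-section-based codes.  Consequences visible in the
package's own measurements: primary-species depletion and H2/H2O2
enhancement at close proximity are strong (tens of percent), but the
non-monotonic H2O2 behaviour -- enhancement turning into depletion once the
second track's solvated electrons find mostly accumulated peroxide -- only
appears at the longest delay simulated (1 us) and with a magnitude of a few
percent, at the edge of Monte Carlo resolution for desk-scale ensembles.
Passing tests therefore demonstrate the mechanism and the machinery, not
quantitative agreement with any published curve.

## Problem sizes used by the tests and the acceptance script

The shipped checks run track segments at LET 30 keV/um over a reduced
0.25 um depth with 12--30 replicates; $\Delta G_{\mu s}$ is intensive, so
depth reduction costs statistics, not effect size.  The isolated-pair
oracle uses 1e4 geminate pairs spaced 1 um apart in one state; the
well-mixed oracle uses 2 x 2000 particles in a 33.5 nm periodic cube over
a 200 ps window at fixed dt = 0.1 ps, sized so that the transient
(time-dependent) part of the Smoluchowski rate stays within a few percent
of the steady-state value being tested.

## Known limitations

* No oxygen or scavenger chemistry, no unimolecular decays, no
  Onsager/field effects, no temperature dependence.
* Two parallel tracks only; non-parallel geometries and >2 tracks are out
  of scope.
* The prechemical branching ratios and the event energy are placeholders;
  absolute yields should not be compared against experiments without
  recalibrating them in the configuration file.
* No secondary-particle equilibrium modelling: the transverse profile is a
  distributional stand-in for the scatter volumes of a full transport
  simulation.
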