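---
title: "Simulating water sorption in coarse-grained protein-like matrices"
author: "hydrosorb authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating water sorption in coarse-grained protein-like matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Amorphous protein powders take up and release water with pronounced
hysteresis: at the same hydration level `h` (grams of water per gram of dry
matrix), the relative humidity measured while wetting (adsorption) differs
from that measured while drying (desorption). Two structural constraints are
known to reshape this behaviour: non-local disulfide-like crosslinks, which
rigidify the matrix and shrink the hysteresis loop, and backbone (chain)
connectivity, whose removal — a free amino-acid mixture instead of a protein
— markedly increases the water uptake capacity at a given humidity.

`hydrosorb` reproduces this phenomenology at desk scale with a deliberately
coarse model: single-site Lennard-Jones "water", two classes of matrix beads
(hydrophilic and hydrophobic, distinguished by a multiplier on the
water–bead well depth), harmonic chain bonds as the backbone analog, and
harmonic non-local crosslinks as the disulfide analog. Everything runs in
reduced Lennard-Jones units (water `sigma = epsilon = k_B = 1`); particle
masses carry gram-scale values only so that `h` can be reported in g/g.

## The sorption protocol

The isotherm is traced one molecule at a time, mimicking the
simulation-based sorption protocol for flexible matrices:

* **Adsorption** inserts each water *continuously*: the molecule appears at
  a non-overlapping random position as a non-interacting ghost
  (`lambda = 0`) and its coupling is ramped linearly to 1, with Metropolis
  relaxation between increments. The configurational energy is
  `U(lambda) = U_rest + lambda * U_inserted(lambda)`. `U_inserted` uses a
  separation-shifted soft core, `r_eff^2 = r^2 + alpha (1 - lambda)
  sigma^2` with `alpha = 0.5`, so the energy stays finite at any overlap for
  `lambda < 1` and reduces *exactly* to the plain pair potential at
  `lambda = 1`. The bare `lambda * U` form diverges for overlapping
  insertions; the soft core is our reading of the underspecified
  `U_inserted(lambda)` and the standard alchemical practice.
* **Desorption** removes one water per cycle, chosen with probability
  proportional to `exp(-beta dU_i)` where `dU_i` is the energy change of
  removing water `i` — loosely bound molecules leave first — followed by
  relaxation. (The same Boltzmann-weighted removal also performs the initial
  dehydration of a freshly solvated powder.)
* Every time the trajectory crosses a hydration grid point (`0.02` g/g
  spacing by default), a longer production relaxation is run; its tail
  frames (after discarding the first 1/7) feed the analysis and the
  chemical-potential estimate.

Relaxation is Metropolis Monte Carlo at fixed N, V, T rather than
barostatted molecular dynamics: at this scale the sorption physics does not
require pressure coupling, and MC gives a provably stationary distribution.
The reference protocol's relaxation times (200 ps per removal, 400 ps per
insertion ramp, 700 ns per saved point) map onto configurable sweep counts
with defaults 200 / 400 / 5000.

One deliberate model ingredient deserves emphasis: a fraction (default
20%) of the trial moves of *free molecules* — waters, and beads carrying
neither bonds nor tethers, i.e. the free amino-acid analogs — are
*relocations* to a uniformly random point rather than local displacements.
The proposal is symmetric, so detailed balance is untouched; physically it
encodes the fact that small molecules diffuse orders of magnitude faster
than a glassy chained matrix relaxes. Without it, slow water
redistribution produces a large branch asymmetry of its own that is blind
to matrix rigidity and masks the structural signal, and the free-bead
mixture cannot disperse on the protocol timescale and never realizes its
entropic uptake advantage. Bonded beads always move locally.

## Chemical potential and relative humidity

At every grid point the water chemical potential is estimated by Bennett's
acceptance ratio over ghost moves that never perturb the trajectory: test
insertions at uniform random positions (forward work) and test deletions of
every real water in every frame (reverse work). The self-consistent Bennett
equation is solved by bracketed root finding on a monotone residual to
below 1e-10; with no waters present the estimator falls back to Widom
insertion with a warning. The desk-scale default is 1e5 test insertions per
grid point (the atomistic reference uses 2e7 per frame; the counts are
configurable). Deletions number one per water per frame, matching the
reference convention. Insertions and deletions from the production frames
straddle the N and N+1 water states; we attribute the estimate to the
saved `h`, the standard reading at these system sizes.

Relative humidity is `RH = 100 exp((mu_w - mu_sat) / (R T))`. The total
chemical potential adds the ideal term `kT ln(rho_w Lambda^3)` at the
frame's water density; the thermal-wavelength reference `Lambda^3` cancels
between `mu_w` and `mu_sat` (asserted numerically over five decades in the
tests), so its value is immaterial as long as both use the same one.

The toy water has no tabulated vapor pressure, so the saturation reference
is a model calibration: `mu_sat = kT ln(rho_vap Lambda^3) + mu_ex(vapor)`,
with `calibrate_mu_sat()` measuring `mu_ex(vapor)` by Widom insertion in a
dilute pure-water box. For the truncated Lennard-Jones water at the default
`T = 0.75` we use a coexistence vapor density of `0.0035 sigma^-3`
(`mu_ex(vapor)` is negligible there). This value is consistent both with
published Lennard-Jones coexistence data at this temperature and with the
chemical-potential plateau our own hydrated runs reach once bulk-like
water accumulates; for real-unit analyses the documented reference is the
vapor pressure of the rigid three-site water model at 300 K, 0.01 bar.

## The synthetic matrix generator

`generate_matrix()` builds `n_chains` self-avoiding random-walk chains of
`chain_length` beads in a periodic box at a target bead density, assigns a
`hydrophilic_fraction` of beads the high water affinity, adds harmonic
chain bonds unless `bonded = FALSE`, and samples crosslink pairs uniformly,
without replacement, among *eligible* pairs — spatially proximal beads that
are sequentially distant (chain separation > 2) or on different chains —
until `crosslink_fraction` of the beads carry one. Each crosslink's rest
length is the pair's separation at generation time, locking the generated
geometry the way an oxidized disulfide locks a fold. A short seeded
annealing relaxation follows. Every generator is bit-deterministic given
its seed.

Key model constants, with the reasoning behind the defaults:

| constant | default | rationale |
|---|---|---|
| bead mass | 110 | one bead per residue, average residue mass |
| water mass | 18 | water |
| bead sigma | 1.2 | residues are larger than water |
| bead epsilon | 0.8 | condensed but responsive matrix at `T = 0.75` |
| philic affinity | 3.0 | hydrophilic sites out-compete water–water attraction |
| phobic affinity | 0.4 | hydrophobic sites weakly wetted |
| hydrophilic fraction | 0.4 | hydrophilic residues drive sorption |
| crosslink fraction | 0 (knob) | 0.2 mirrors a cysteine-rich protein |
| bead density | 0.15 | leaves pore volume for water up to ~0.5 g/g |
| temperature | 0.75 | liquid water regime (`T/T_c` comparable to ambient water) |
| cutoff | 3.0 sigma | plain truncation, no tail correction |

The defaults for `bead_epsilon` and `philic_affinity` were fixed by two
physical calibration targets taken from the phenomenon itself, *before*
any hysteresis comparison: (i) the dry annealed matrix must be a condensed
powder, and (ii) hydrating it to 0.3 g/g at equilibrium must visibly
increase its solvent-accessible surface area, with the increase suppressed
when crosslinks are present — the structural mechanism through which
rigidity acts. With the original trial values (`epsilon = 1.0`, affinity
1.8) water condensed into a droplet beside an inert matrix and no
structural response existed for rigidity to suppress.

## What the validation runs do and do not show

The acceptance suite runs the full pipeline at a reduced scale chosen to
keep the whole suite within a desktop-scale run: a 200-bead matrix
(10 chains of 20 beads, or 200 free beads), a 2.5 sigma cutoff, a
2000-sweep anneal, and ten paired seeds per comparison. The rigidity
comparison covers 0.04–0.24 g/g with 12 relaxation sweeps per removal, 15
per insertion ramp (3 lambda increments), 120 production sweeps per grid
point and 1.5e4 test insertions; the connectivity comparison covers
0.04–0.45 g/g on the adsorption branch with 6/8/80 sweeps and 1e4
insertions. At this scale:

* the flexible matrix shows a clear hysteresis loop whose structural
  signature — the desorption branch stays swollen (higher SASA) at the
  same `h` where the adsorption branch is still compact — disappears when
  every bead is tethered (a fully rigid control), and shrinks when 20% of
  beads carry crosslinks;
* the free-bead mixture (no chain bonds) reaches a given relative humidity
  at higher hydration than the bonded matrix, through the dispersal and
  enhanced solvation of unconstrained beads;
* the largest-water-cluster fraction rises sigmoidally with `h` from
  isolated pockets to a dominant, eventually spanning network.

These are *qualitative* reproductions of the reference phenomenology as
emergent properties of a toy model. Quantities tied to atomistic detail —
saturation hydration levels of specific proteins, absolute RH positions of
the loops, residue-specific hydration sites — are outside what this model
can or tries to reproduce. Stochastic comparisons at this scale retain
seed-to-seed variability; the suite therefore asserts majorities over
paired replicates, not point values.

## Numerical choices

* Particle indices are 1-based throughout the R interface; the C++ kernels
  convert internally. Positions are wrapped to `[0, L)`; minimum-image
  displacements use `d - L floor(d/L + 1/2)`, placing components in
  `[-L/2, L/2)`.
* Matrix beads always precede waters in the particle order, so bonded
  topology indices survive water insertion and removal.
* The Metropolis kernel uses a sub-cell neighbour list (cell edge about
  half the cutoff, neighbour offsets selected by box-to-box minimum
  distance) updated incrementally on accepted moves; small or non-periodic
  boxes fall back to a plain O(N) loop. Both paths give identical energies
  up to summation order, which the tests check against plain double loops.
* Bonded pairs are excluded from the Lennard-Jones sum; bonds are
  `0.5 k (r - r0)^2`.
* The removal sampler normalizes Boltzmann weights after subtracting the
  maximum exponent and draws by inverse CDF with a single uniform variate
  over the stable particle ordering.
* BAR brackets its root by geometric expansion around the Widom estimate;
  the residual is strictly monotone, so the root is unique.
* Block averages drop trailing remainder elements; the default is 5 blocks.
* `first_minimum()` refines the binned minimum with a parabola through the
  three neighbouring bins.
* SASA uses a golden-spiral lattice (default 960 points); the reference
  algorithm for the published maps is unstated, so Shrake–Rupley with a
  1.4 Angstrom probe is assumed for real-unit inputs, 0.5 sigma for
  reduced units. Interior cavity surface is counted; waters are excluded
  from the surface set by default because water is the solvent.
* Cluster cutoffs: 3.5 Angstrom (water–water), 4.3 (bead–water) and 6.3
  (bead–bead) for Angstrom-unit inputs; reduced-unit runs derive cutoffs
  from the first minima of the corresponding radial distribution functions
  via `derive_cutoffs()`, mirroring the reference procedure (the
  water–water first minimum of the toy liquid sits near 1.5 sigma).
* Distance maps average within each chain copy and then over copies when
  `average_chains = TRUE`; whether the published per-protein maps average
  over powder copies is not stated, so the convention is ours and
  documented.
* Sorption runs save frames every 10 sweeps of production by default
  (after discarding 1/7), echoing the use of the final six-sevenths of the
  reference production window.
* The desorption step removes the selected water discretely and then
  relaxes; the reference gradually decouples it. The discrete variant is
  the protocol's removal move throughout (it is also what the reference
  uses for initial dehydration); at the relaxation lengths used here the
  two differ only in the brief transient after each removal.

## Known limitations

* Fixed N, V, T: no barostat, so the box does not breathe with hydration;
  swelling shows up in SASA and inter-residue distances instead of volume.
* No electrostatics; attraction heterogeneity lives entirely in the
  affinity multiplier.
* Chains are freely jointed: there is no bending stiffness or secondary
  structure, so "rigidity" from crosslinks is weaker than in a folded
  protein with the same crosslink density, and the rigidity contrast at
  desk scale is correspondingly gentler than the published one.
* The Widom fallback (zero waters) and the BAR estimate share the ideal
  term convention `kT ln(rho_w Lambda^3)` with `rho_w = N_w / V`; at very
  small water counts the `N` vs `N+1` ambiguity in the ideal term is of
  order `kT/N_w`.
* Test insertions sample the whole box uniformly; in a nearly filled box
  most insertions land in repulsive cores and the estimator degrades
  gracefully (larger stderr) rather than failing.
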