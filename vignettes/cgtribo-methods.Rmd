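---
title: "Methods: coarse-grained parametrization, simulation and tribology analysis with cgtribo"
author: "cgtribo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained parametrization, simulation and tribology analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`cgtribo` is a toolkit for studying boundary lubrication by
polyelectrolyte–surfactant films at coarse-grained (MARTINI-style)
resolution.  It covers the full workflow for a cationic polysaccharide
(guar hydroxypropyltrimonium chloride, "CGG") interacting with an anionic
surfactant (SDS) and water on grafted biomimetic surfaces:

1. **Bottom-up parametrization** — map atomistic reference trajectories
   onto beads (about four heavy atoms per bead, hydrogens folded into
   their heavy atoms) and fit harmonic bonded terms by Boltzmann
   inversion.
2. **System building** — polymer chains with a configurable degree of
   substitution (DS), 4-bead SDS, polarizable 3-site water, hydrated
   counterions, grafted model surfaces, and mirrored confined contacts.
3. **Desk-scale coarse-grained MD** — velocity-Verlet dynamics with
   Langevin or Nosé–Hoover thermostats, SHAKE constraints, force-switched
   Lennard-Jones and damped force-shifted Coulomb interactions,
   confinement under constant normal load and wall sliding.
4. **Tribology analysis** — through-film mass/charge/number/velocity
   profiles, film thickness and hydration, surface coverages and charge
   ratios, radius-of-gyration scaling, shear stress, and friction-law
   fits (velocity power law and the extended Amontons law
   τ = μσ + τ₀ with Derjaguin offset τ₀).

Internal units are GROMACS-style — kJ/mol, nm, ps, amu, elementary
charge — in which 1 kJ/mol equals 1 amu·nm²/ps², so the equations of
motion carry no conversion factors.  LAMMPS data and dump files are
exported in LAMMPS "real" units (Å, kcal/mol, fs) through one audited set
of constants (`cg_constants()`).

# Functional forms

**Lennard-Jones.**  Nonbonded pairs interact through a 12-6 potential
whose force is switched smoothly to zero between `r_on = 0.9` nm and
`r_cut = 1.2` nm using the standard cubic/quartic force-switch
polynomial; the energy follows by integration, so energy and force are
continuous everywhere and exactly zero at and beyond the cutoff.  The
switch radii are the conventional MARTINI 2 values and are configurable
via `shift_spec()`.  Pair (ε, σ) values are looked up in a symmetric
class table (`lj_pair_table()`); missing pairs fall back to
Lorentz–Berthelot combination.  The shipped `default_lj_table()` is a
small generic level-of-interaction table sufficient for liquid-like
packing in tests; production parametrizations should supply their own
published values — the table is deliberately an input, not a constant of
the package.

**Bonded terms.**  Bonds and angles are harmonic.  Force constants are
stored in the *half-included* convention (E = K·Δ², the LAMMPS
convention in which quoted constants already include the factor of ½);
the *explicit-half* (GROMACS) dialect is supported everywhere through a
convention flag, and conversion is an exact factor of two.  Dihedrals
are deliberately not implemented: coarse-grained polysaccharide models
of this resolution typically omit them for numerical stability, and the
package follows that practice.

**Electrostatics.**  Point charges interact through a damped
(erfc-screened), force-shifted Coulomb potential with a finite cutoff:
E and F are shifted so both vanish continuously at `r_cut`.  This is the
package's single largest fidelity compromise relative to mesh (Ewald/PPPM)
electrostatics.  At desk scale the qualitative electrostatic phenomena
of this system — ion pairing, counterion condensation, complexation of
anionic heads with cationic monomers — survive the approximation; mesh
methods are out of scope by design.

**Exclusions.**  First bonded neighbours (bond or constraint partners)
are excluded from nonbonded interactions; second neighbours interact.
The polarizable water template carries an explicit full intramolecular
exclusion list, matching the published three-site polarizable model.

# Boltzmann inversion

`fit_harmonic_bond()` and `fit_harmonic_angle()` implement Gaussian
moment matching: the Boltzmann distribution of a half-included harmonic
term at temperature T is Gaussian with mean x₀ and variance
k_B·T/(2K), so

* x₀ = sample mean,
* K = k_B·T / (2·Var(x)), with the population (maximum-likelihood)
  variance.

Moment matching was chosen over least squares on −k_BT·ln P(x) because
it is robust to histogram noise in the tails and is the documented
behaviour of the established inversion tools this module emulates.  K is
exactly linear in the inversion temperature (default 300 K, from
configuration).

**Angle Jacobian.**  Angles sampled from three-dimensional
configurations carry the spherical volume element sin θ.  With
`jacobian = TRUE` (default) samples are reweighted by 1/sin θ before
moment matching, recovering the bare potential parameters; samples at
exactly 0 or π are dropped with a warning.  For data generated directly
from one-dimensional Gaussians (as the synthetic fixtures do) the flag
should be off — it must match the measure the samples were drawn from.

**Histograms.**  Fitting always uses raw samples; histograms
(Freedman–Diaconis by default in reports, a fixed common grid in
`compare_distributions()`) are for reporting and overlap computation
only.  The overlap coefficient is the integral of the pointwise minimum
of the two normalized histograms, in [0, 1].

# Builders

**Chains.**  A monomer contributes 9 beads (a 6-bead two-ring backbone
segment and a 3-bead side sugar); a functionalized monomer adds a P1
hydroxypropyl bead and a Q0 trimethylammonium bead carrying +1 e.
`round(DS · n_repeat)` monomers are functionalized, chosen uniformly at
random without replacement (or regularly spaced).  Backbone beads are
placed by a self-avoiding random walk with fixed step length (default
0.47 nm): candidate steps closer than `min_dist` (default 0.3 nm) to any
non-bonded placed bead are resampled, with a retry cap that converts
infeasible requests into an informative error.  Every build is
deterministic given (spec, seed).  The exact bead membership of the
cationic substituent cannot be fixed from first principles at this
resolution; the layout above is one defensible assignment and the
mapping module is config-driven so alternatives are expressible.

Molecular weight bookkeeping uses bead masses (72 amu per standard
bead), so a 50-repeat DS = 100% chain has a bead-mass total that differs
from the chemical molar mass of the real repeat unit; both can be
reported, and neither is asserted against a particular chemical value.

**Water.**  The polarizable three-site water has a central LJ bead and
two satellites at 0.14 nm on constrained bonds, a harmonic angle with
θ₀ = 0° and K_Θ = 2.1 kJ·mol⁻¹·rad⁻² (half-included), satellite charges
±0.46 e, and 24 amu per bead — geometry and angle constant as published
for the polarizable coarse-grained water model, with bead masses and
charges from the same source.

**Surfaces.**  The grafted surface is a deliberately simplified stand-in
for validated biomimetic hair-surface models: a rigid anchor lattice at
z = 0 with `round(density·area)` grafted linear chains, an anionic
fraction of graft heads (0 for virgin-like apolar monolayers, > 0 for
bleached-like oxidized ones) and neutralizing counterions.
`make_contact()` mirrors the (surface + adsorbate) assembly through the
mid-plane — reflection twice is the identity, bead count exactly doubles
— producing the two-surface confined geometry used for squeeze-out and
sliding.

**Bulk assembly.**  Random insertion with uniform random rotations and a
0.3 nm overlap tolerance (≈ the smallest bead σ) prevents LJ blow-up at
start-up; neutralization adds hydrated Na⁺/Cl⁻ beads so the net charge
is exactly zero in integer arithmetic.

# The MD engine

The integrator is velocity Verlet arranged as a B–A–O–A–B splitting.
With the Langevin thermostat the O step is the exact Ornstein–Uhlenbeck
update `v ← c·v + sqrt((1−c²)·k_BT/m)·ξ`, `c = exp(−dt/damping)`, which
keeps the sampled kinetic temperature accurate to O(dt²) and reduces
exactly to velocity Verlet as damping → ∞.  The noise can be restricted
to axes (e.g. y only, the convention for sliding simulations so the
thermostat does not fight the flow) and to a bead group (e.g. graft base
beads).  A single-variable Nosé–Hoover scheme is provided for
equilibrium runs.  The default time step is 5 fs, standard for MARTINI
dynamics.

SHAKE iterates pair constraints to a configurable tolerance (default
10⁻⁸ nm) after each position half-step, with RATTLE velocity projections
after velocity updates; both apply equal and opposite corrections, so
momentum is conserved.  Constrained molecules (water) therefore keep
their geometry to well below 10⁻⁶ nm per step.

Nonbonded interactions use a Verlet neighbour list (cell-binned build,
0.3 nm skin) rebuilt on a two-largest-displacement criterion.  The RNG
is a self-contained splitmix64/Box–Muller pair, so identical
(state, config, seed) inputs give bit-identical trajectories on a given
platform.

**Confinement and sliding.**  Beads tagged `lower_anchor` are frozen;
beads tagged `upper_anchor` form a rigid sheet with one collective
vertical degree of freedom, loaded with total force σ·A distributed over
the sheet and driven at constant sliding velocity v_s along x
(σ in MPa and v_s in m/s are converted internally by
`cg_constants()$mpa_to_internal` and ×10⁻³).  The log records the
anchor-sheet gap and the normal/lateral interaction forces on both
anchors as *interval means over every integration step* between samples
— wall forces are noisy, and per-step averaging is what makes the piston
force balance and shear stress converge at desk scale.  An optional
one-sided harmonic repulsive wall (configurable strength) closes the top
of non-periodic boxes during adsorption runs; a harmonic form was chosen
because it is the simplest boundary with continuous forces.

# Analysis layer

* `traj_profile()` bins mass, charge, number or x-velocity along the
  surface normal; default bin width 0.1 nm (finer than σ/4, resolving
  layering without empty-bin noise at desk scale).  Velocity bins with
  zero occupancy are `NA`, never zero.  Profile sums times bin volume
  reproduce the selected totals to 10⁻⁸ relative (conservation).
* `film_thickness()` is the distance between the 1% and 99% quantiles of
  the cumulative density (the span containing 98% of the film mass),
  linearly interpolated inside bins.  On a uniform slab of 10 nm this is
  exactly 9.8 nm; on a unit Gaussian 2 × 2.3263 = 4.653 nm.
* `hydration_fraction()` is the water mass fraction inside the film's
  quantile extent.
* `coverages()` reports areal densities (water counted as coarse-grained
  beads per nm², surfactant and polymer as molecules per nm²; the choice
  for water is documented here because the two conventions differ by the
  beads-per-molecule factor) and the charge ratios R_SDS (surfactant
  anions per polymer cation) and |R_surf| (surface anions per polymer
  cation).
* `shear_stress()` averages the lateral anchor force over a steady-state
  window (a configuration parameter, default the second half of the
  record) with a 5-block standard error — five equal blocks everywhere,
  simple and reproducible.
* `fit_powerlaw()` fits ln τ against ln v_s (the velocity-weakening /
  strengthening exponent); the window `v_min` excludes slow points
  outside the power-law regime and is always reported with the fit.
* `fit_amontons()` is ordinary least squares τ = μσ + τ₀ with τ₀
  unconstrained in sign.
* `rg_scaling()` fits ln⟨Rg⟩ against ln M_w after averaging duplicate
  molecular weights.
* `interdigitation_overlap()` integrates the pointwise minimum of two
  opposing layer profiles — a scalar that grows monotonically as the
  layers interpenetrate under load.

# Synthetic fixtures: what they emulate and what they do not

The fixtures module gives every downstream stage a statistically
controlled input with known ground truth:

* `gen_boltzmann_samples()` — exact Gaussian samples of a harmonic
  coordinate.
* `gen_pseudo_atomistic_traj()` — a bead skeleton sampled from target
  bond/angle distributions with member atoms placed rigidly around each
  bead centre at zero mass-weighted offset, so mapping recovers the
  skeleton to machine precision and fitting recovers the generating
  parameters.  It emulates the *statistics* of an atomistic reference
  trajectory, not its energetics: there are no excluded-volume
  correlations between non-bonded atoms, no solvent, and bond/angle
  samples are drawn independently per frame (no dynamics).
* `gen_confined_film_traj()` — Gaussian layer mixtures in z with a
  linear Couette velocity profile plus optional noise; uniform in the
  lateral plane, uncorrelated between frames.
* `gen_friction_dataset()` — τ(σ, v_s) = (μσ + τ₀)(v_s/v_ref)^α with
  multiplicative lognormal noise.

Passing tests on these fixtures therefore demonstrates that the
*measurement and inversion layers are correct and unbiased*, and that
the engine reproduces the statistical mechanics of its own model — not
that the coarse-grained model reproduces any particular experimental
system.  Generators use one seed with counter-derived substreams per
species, so adding a species does not perturb the others.

# Numerical choices and degenerate inputs

* Zero-variance bond/angle samples are rejected with a suggestion to use
  a constraint instead of a bond.
* Angles with a zero-length arm are skipped per frame with a warning;
  collinear configurations use a clamped arccosine and a sin θ guard in
  the force kernel.
* SHAKE failure to converge within 500 iterations is an error naming the
  molecule, not a silent continuation.
* Cutoffs larger than half the smallest periodic box edge are rejected
  (minimum-image validity).
* Non-finite forces abort the run naming the bead.
* Insertion and walk retry caps convert infeasible packing requests into
  errors suggesting remedies.

# Closed-loop validation and its reference measure

The distribution closed loop (fit → simulate → collect → compare)
compares simulated bond/angle marginals against *direct Monte Carlo from
the Boltzmann measure of the fitted model including the r² and sin θ
volume elements* (rejection sampling), not against bare 1-D Gaussians.
The chain ensemble genuinely carries those Jacobians — a bond marginal
is tilted by r², shifting its mode by 2σ²/r₀ — and comparing against the
bare Gaussian would book that physical tilt as integrator error.  The
bare-Gaussian comparison is still available (it is what
`gen_boltzmann_samples()` produces) and differs from the
Jacobian-corrected one by a few percent at typical stiffnesses.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely at desk scale,
sizes chosen so that statistical errors sit well inside the tolerances
being asserted: inversion round trips use 5×10⁴ frames; the closed loop
simulates a 10-bead chain for 10⁶ steps; the thermostat check uses a
125-bead LJ fluid for 1.1 ns; the confined-film oracles (piston balance,
Couette linearity) use a ~590-bead film — 80 000 equilibration steps
under 30 MPa, then 300 000 (piston) and 260 000 (sliding) production
steps; the ideal-chain limit simulates chains of 6, 12 and 24 beads for
2–9 ×10⁶ bonded-only steps, several hundred Rouse times each.  The
freely jointed chain obeys ⟨Rg²⟩ = b_eff²(N²−1)/(6N) with
b_eff² = ⟨r²⟩ of the radially weighted bond distribution (computed by
quadrature in the tests, a ~0.5% correction over the bare b²).

# Known limitations

* Finite-cutoff electrostatics (no Ewald/PPPM): long-wavelength
  electrostatic correlations and exact slab corrections are absent.
* No barostat: bulk preparation uses fixed boxes sized by the builder.
* The grafted surface is a minimal configurable monolayer, not a
  validated multi-component biomimetic surface model.
* Production-scale squeeze-out and sliding systems (10⁵–10⁶ beads) are
  out of the package's intended envelope; the engine is single-threaded
  and desk-scale by design.
* Micelle self-assembly may occur in-engine but micelles are not
  pre-constructed; preformed-complex adsorption pathways are not
  modelled.
* Dihedral potentials and tabulated interactions are not implemented.

# A minimal end-to-end example

```{r, eval = FALSE}
library(cgtribo)

## 1. fit bonded parameters from a (synthetic) atomistic reference
sch <- mapping_scheme(list(RES = list(
  list(name = "B1", type = "P4", atoms = c("C1", "C2", "C3", "O1")),
  list(name = "B2", type = "P1", atoms = c("C4", "C5", "O2")),
  list(name = "B3", type = "P4", atoms = c("C6", "C7", "C8", "O3")))))
g  <- gen_pseudo_atomistic_traj(sch,
        list(bond = list(r0 = 0.47, K = 600),
             angle = list(theta0 = 2.0, K = 30)),
        n_frames = 2e4, seed = 1)
ds <- collect_distributions(map_trajectory(g$traj, sch), g$topology)
tab <- boltzmann_invert(ds, jacobian = FALSE)
write_parameter_table(tab, "cgg_bonded.itp")

## 2. build a small confined contact
surf <- build_graft_surface(surface_spec(8, 8, graft_density = 0.5,
                                         anionic_fraction = 0.5), seed = 1)
contact <- make_contact(surf, gap = 6)

## 3. squeeze and slide
eq <- run_confined(init_velocities(contact, 300, seed = 2),
                   integrator_config(dt = 0.005, thermostat = "langevin",
                                     T_target = 300, seed = 3),
                   load_slide_config(sigma = 10, v_s = 0), n_steps = 5e4)
sl <- run_confined(eq$state,
                   integrator_config(dt = 0.005, thermostat = "langevin",
                                     axes = "y", seed = 4),
                   load_slide_config(sigma = 10, v_s = 100),
                   n_steps = 1e5, frame_every = 200)

## 4. measure
shear_stress(sl)
traj_profile(sl, quantity = "mass")
```
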