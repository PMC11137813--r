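---
title: "Coordination force fields for heme-gas-ligand models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordination force fields for heme-gas-ligand models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemeforge)
```

## The problem

Classical protein force fields describe nonbonded contacts well but have no
term for the dative coordination bond between the heme iron and a gas ligand
(CO or O~2~). hemeforge implements a parametrization pipeline for exactly
that term: a pair-specific 12-6 Lennard-Jones override (the NBFIX mechanism
of CHARMM-family force fields) whose two parameters are fitted so that the
classical model reproduces a reference energy/force curve along the
iron-ligand axis. On top of the fitted parameters the package provides the
biased-sampling machinery used to interrogate the resulting bond: steered
pulling to rupture, and well-tempered metadynamics over the two bond-length
collective variables of the CO/O~2~ competition.

Reference electronic-structure curves are not bundled; a synthetic
ground-truth generator (`synthesize_ground_truth_curve()`) produces
tabulated U(r) curves from known parameters, optionally with a smooth
background and seeded noise, standing in for quantum-chemistry data in every
test and example.

## The direct fit (single-site path)

The coordination-only force curve is obtained by subtraction
(`extract_coordination_force()`): the force evaluated with the full
reference method minus the force evaluated with the classical baseline whose
iron-ligand well depth has been zeroed. Forces come from tabulated energies
via the adjacent-difference rule

$$F_i = -\frac{U_{i+1} - U_i}{\Delta r}, \qquad \Delta r = 0.1\ \text{Å},$$

assigned to the left grid node (`finite_difference_force()`). The rule is
first order: a single interval with an outsized energy jump leaves a
characteristic spike in the force curve, which is why `fit_lj_to_force()`
accepts a point mask.

`fit_lj_to_force()` then minimizes
$\sum_i [F_{LJ}(\epsilon, \sigma; r_i) - F_{crd}(r_i)]^2$ over the window
1.75--2.95 Å with bounded Levenberg-Marquardt (via minpack.lm) and a
multistart over $\sigma$, which avoids the repulsive-wall local minimum.
Two conventions are supported throughout, because parameter tables in the
literature print "$\sigma$" for either meaning: the textbook sigma form
$4|\epsilon|[(\sigma/r)^{12} - (\sigma/r)^6]$ (default) and the CHARMM
R~min~ form. All roundtrips are convention-consistent; neither is asserted
to be the "true" reading of any published table.

**Finite-difference-consistent fitting.** The forward difference assigned
to the left node estimates the force at roughly $r_i + \Delta r/2$. Fitting
the *analytic* LJ force to such data therefore biases $\sigma$ by about
0.05 Å — two orders of magnitude above the optimizer's own precision. When a
curve was produced by `finite_difference_force()` (the curve carries a
marker), the model force is differenced with the same rule on the same grid
(`model = "auto"`), making generate-then-fit roundtrips exact. `model =
"analytic"` remains available for data that are true point forces.

## The reduced complex

All dynamics run on a coarse stand-in for the six-coordinate
heme–imidazole–ligand complex (`build_complex()`): iron at the origin; the
porphine ring as four pyrrole nitrogens (Fe–N 2.0 Å) plus eight alpha and
four meso carbons (3.05 / 3.42 Å, idealized D4h geometry) in the z = 0
plane; an axial imidazole nitrogen at −2.1 Å; rigid CO (1.128 Å) and/or O~2~
(1.21 Å) above the plane, on the same side when both are present. The two
oxygen atoms are distinct species: `o2` is proximal (bond-forming), `o1`
distal, and that identity is preserved everywhere downstream.

The full ring-carbon shell matters: with only the four nitrogens the ring
surface is azimuthally corrugated and a restrained O~2~ can lodge in the
gaps between them, an artifact of over-coarsening rather than a feature of
the chemistry.

Energetics are deliberately minimal: the coordination NBFIX pairs
(`coordination_params()`, shipped defaults ε = −21.49/σ = 1.79 Å for
Fe–C(CO), −4.37/2.74 for Fe–O¹, −6.55/1.90 for Fe–O²), plus generic
per-element van der Waals terms (`generic_vdw_params()`: C 0.11/2.0, O
0.12/1.7, N 0.20/1.85, Fe 0.01/1.3 kcal/mol and R~min~/2 Å,
Lorentz–Berthelot combination) acting between molecules. These generic
terms carry the CO–O~2~ steric competition. There are no partial charges,
no water, and no protein pocket; the consequences are discussed under
*Limitations*.

The geometry values are plausible placeholders for optimized internal
coordinates, exposed in `complex_geometry()` rather than hard-coded.

## Dynamics engine

`run_langevin()` integrates the mobile sites (the ligands; the scaffold is
fixed, isolating the coordination degrees of freedom the parameters govern)
with a BAOAB Langevin splitting, SHAKE/RATTLE for the rigid diatomics, and
CHARMM-style switching of all pair terms between 8 and 10 Å (inert at this
system size, but kept so the pair kernel honours the standard nonbonded
contract). Defaults: 2 fs step, 300 K, friction 5 ps⁻¹. All randomness is
drawn from R's RNG, so a seed makes every trajectory bitwise reproducible.

Numerical behaviour worth knowing: the kinetic temperature of a free rigid
rotor or of the CO complex converges to the target within sampling error;
the stiffest configurations (O~2~ pressed into its deep proximal well plus
ring contacts) show a few percent of discretization heating at 2 fs. The
configurational averages used as features are robust to this; the
database and any inversion target are always featurized with the identical
protocol, so the mapping is self-consistent.

`energy_scan()` is the static counterpart: the ligand is rigidly translated
along the plane normal and the total potential energy recorded
(a step-0 evaluation), with overlap-flagged grid points.

## Inverse design of the two-site O2 model

A single fitted pair cannot simultaneously reproduce the energy curve and
the equilibrium Fe–O²–O¹ angle, which motivates distinct proximal/distal
parameters and an inverse problem: find $(\epsilon_1, \sigma_1, \epsilon_2,
\sigma_2)$ from three observables. The package implements the full loop:

1. `sample_param_database()` draws records uniformly (rejection sampling)
   from the admissible box: 8 < ε₁+ε₂ < 12 kcal/mol, 0.3 < ε₁/ε₂ < 0.6,
   2.5 < σ₁ < 3 Å, 1.8 < σ₂ < 2.05 Å. Depths are sampled as magnitudes and
   converted to the signed convention only at the physics boundary.
2. `featurize_record()` computes, per record: the effective single-LJ
   features $(\epsilon_f, \sigma_f)$ by scanning the O~2~ complex at its
   relaxed pose, finite-differencing and refitting one LJ law over the same
   1.75–2.95 Å window; and the mean Fe–O²–O¹ angle over a 20 ps
   equilibrium run sampled in 100 snapshots (2 ps of discarded
   equilibration precede the window). Records whose effective fit fails to
   converge are flagged and excluded from training, with counts reported.
   `angle_ps` may be shortened for reduced-cost sweeps; whatever protocol
   is chosen must be (and in this package is) applied identically to the
   database and to any inversion target.
3. `train_fnn()` trains the feedforward network — four fully connected
   layers, 3 → 64 → 64 → 64 → 4, ReLU between all but the output layer,
   Adam at learning rate 5×10⁻⁴ for 2001 epochs, mean-squared-error loss —
   on an 80/20 split (12,000 records give exactly 9,600/2,400). Features
   and targets are z-scored on the training partition; unscaled targets of
   mixed magnitude train poorly. The batch size (512, reshuffled each
   epoch) is a free protocol choice recorded in the model. The network is
   implemented directly in R (matrix forward/backprop); the trained model
   serializes to plain JSON with its normalization statistics.
4. `invert_features()` is a single forward pass; targets outside the
   training feature box are flagged as extrapolations.

Two structural facts shape the accuracy you should expect, and both are
visible in the reported per-output RMSEs rather than hidden. First, three
features determine four parameters only through the sampling constraints,
so the distal pair (ε₁, σ₁) is recovered with visibly higher error than the
proximal one. Second, the shipped two-site values have ε₁/ε₂ ≈ 0.667,
outside the sampled 0.3–0.6 band: inverting their features is a mild
extrapolation, and the honest yardstick for that prediction is the model's
own test RMSE, not machine precision. In practice σ₂ comes back almost
exactly while ε₂ carries an extrapolation bias of roughly one test-RMSE:
the network, seeing an effective depth consistent with the constrained sum,
splits it according to the ratio prior it was trained on.

## Biased sampling

`relax_system()` reproduces the pre-pull protocol: 1 ns of equilibration
with an upper wall on Fe–C(CO) (ceiling 1.89 Å, 150 kcal/mol/Å²) and, when
an O~2~-rich environment is simulated, a harmonic restraint with reference
length zero on the Fe–O² distance; its stiffness (1–10 kcal/mol/Å²) sets
how close the O~2~ hovers.

`run_smd()` pulls the Fe–C distance with a moving harmonic restraint
(stiffness 10 kcal/mol/Å², reference length growing at a constant rate from
its relaxed value). The paper-scale rate is 1 Å/ns; desk protocols in this
package use 10 Å/ns, always comparing arms at equal rates, with the rate
recorded in every result. **Peak force** is defined as the maximum of the
spring force over the trace *up to bond rupture* (first crossing of Fe–C =
3.5 Å, configurable). After rupture the freed ligand's spring force is
zero-mean noise with standard deviation $\sqrt{\kappa k_B T}$; the running
maximum of that noise grows with trace length and would otherwise dominate
the statistic without measuring anything about the bond. A replicate that
never ruptures is flagged and falls back to the whole-trace maximum.
`run_smd_sweep()` wraps the full assay (5 seeded replicates per stiffness,
seeds `seed`, `seed+1`, ...; the stiffness-0 control runs without O~2~) and
reports mean ± sd peak force and the time-mean restrained Fe–O² distance
over the pull.

`run_wt_metad()` deposits Gaussians on the (Fe–C, Fe–O²) distance pair:
initial height 8 kcal/mol, width 0.2 Å, one hill per ps, well-tempered
decay $h = h_0 e^{-V/((\gamma-1)k_BT)}$, upper walls at 5 Å / 150
kcal/mol/Å² on both CVs to permit rapid rebinding. The bias factor is not
part of the published protocol; the default here is γ = 10, configurable
and echoed in all outputs. The engine accumulates the bias on a grid for
O(1) force evaluation; `reconstruct_fes()` instead resums the hills log
directly, so the two paths cross-check each other. The free energy is
$F(s) = -\frac{\gamma}{\gamma-1} V(s)$, minimum-shifted to zero.
`slice_effective_bond_energy()` reads, along a constant-Fe–O² slice, the
maximum free energy from the slice minimum outward relative to that minimum
— the barrier to breaking the CO bond in that O~2~ environment — and flags
slices without an interior minimum. The quantity is invariant under
constant shifts of the surface. `approach_pattern()` classifies how the
proximal oxygen approaches the iron (axially versus across the ring
surface) from recorded frames.

Validation harnesses: `simulate_cv_model()` runs the same integrator and
bias machinery on analytic one-dimensional landscapes. The tests require
equipartition in a harmonic well within 10%, a flat landscape reconstructed
flat, a 3 kcal/mol double-well barrier recovered within 0.5 kcal/mol RMS,
and zero-temperature stiff-spring pulling of a bare pair to reach the
analytic maximal attractive force $F_{max} = 2.389\,|\epsilon|/\sigma$
(location $(26/7)^{1/6}\sigma$) within 2%.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run, by choice, at these sizes:
the full 12,000-record database (9,600/2,400 split) and the full 2001-epoch
training; per-record angle windows of 20 ps/100 snapshots in the acceptance
script and 6 ps/100 snapshots in the test suite (both protocols applied
identically to database and target); SMD sweeps of 5 replicates per arm at
10 Å/ns after 1 ns relaxation; metadynamics runs of a few ns on the reduced
complex. The double-well and equipartition oracles use single-particle
runs of a few ns.

## Limitations, honestly stated

* The reduced complex has no solvent, no protein pocket and no
  electrostatics. The most visible consequence: a Fe–O² restraint of
  stiffness 3 kcal/mol/Å² holds O~2~ at ≈ 2.3–2.4 Å here, closer than the
  ≈ 2.8 Å the same stiffness produces in a solvated protein, because
  nothing occupies the first coordination shell. Weakening of the CO bond
  is correspondingly *stronger* at equal stiffness: in this model the
  stiffness-3 environment nearly abolishes the bond (the regime a solvated
  system only reaches at higher stiffness), while the ≈ 2.8 Å O~2~
  environment arises near stiffness 1 and reduces the peak force to
  roughly three quarters. The stiffness-to-distance mapping, not the
  distance-to-weakening physics, is the model-dependent step. Passing
  tests on this model demonstrate the machinery and the qualitative
  competition physics, not solvated-protein numbers.
* The equilibrium-angle feature carries sampling noise of a degree or two
  at 20 ps; it enters training data and targets alike.
* The inverse network's distal-pair outputs are weakly determined by
  construction (three features, four parameters); treat ε₁, σ₁ as
  indicative.
* Kinetic temperature of the stiffest O~2~ configurations runs a few
  percent hot at the 2 fs step; configurational features are unaffected
  for the purposes used here.
* Rupture forces are rate- and definition-dependent; compare only at equal
  rates and with the documented rupture-bounded peak definition.
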