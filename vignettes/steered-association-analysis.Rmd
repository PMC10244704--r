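---
title: "Steered cofactor association, pocket volumetrics and contact occupancy with steermd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steered cofactor association, pocket volumetrics and contact occupancy with steermd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steermd)
```

## Scope and model

`steermd` analyses how readily a methyl-donor cofactor (AdoMet) associates
productively with a SET-domain lysine methyltransferase–peptide complex,
and how the active-site pocket geometry controls that association. It
covers four linked analyses — transition-state-like docking detection,
grid-based pocket volumetrics, heavy-atom contact occupancy, and the
accompanying statistics — together with a coarse steered simulator and
synthetic generators that make every stage testable against analytic
ground truth.

The package analyses trajectories; it does not run all-atom molecular
dynamics. The toy simulator exists to exercise the pipeline end to end
with realistic input shapes, not to reproduce force-field kinetics.

## TS-like docking detection

An SN2 methyl transfer requires the attacking nitrogen, the transferred
methyl carbon and the leaving sulfur to line up. A frame is classified as
TS-like when three internal coordinates simultaneously satisfy:

* d(Nε, C_methyl) < 4 Å — strict, following the printed inequality;
* attack angle Cδ–Nε–C_methyl within 109° ± 30° — inclusive bounds;
* linearity angle Nε–C_methyl–S within 180° ± 30° — inclusive.

Angles are computed as folded interior angles in [0°, 180°] via
atan2(|u×v|, u·v) — equivalent to the arccosine of the normalized dot
product but well-conditioned near 180°, where the linearity criterion
lives — so the linearity window is equivalent to angle ≥ 150°. Inclusivity at the angle edges is unobservable
in floating-point practice but is fixed here so the independent oracle in
the test suite is unambiguous. Classification uses only internal
coordinates and is therefore invariant under rigid-body motion, which the
tests verify directly.

A replicate *succeeds* when at least one recorded frame passes; success is
evaluated on recorded frames only, never on interpolated states. Docked
poses are additionally compared to a bound reference by Kabsch
superposition on a receptor fit group followed by RMSD over the cofactor
beads. The choice of fit group (receptor heavy atoms here) and ligand
subset is configuration, not an assertion about any particular published
protocol, which leaves both unspecified.

## The steered toy simulator

The simulator integrates overdamped (first-order) Langevin dynamics,

x ← x + μ F Δt + √(2 kB T μ Δt) ξ,  μ = 1/(m γ),

with per-bead mobility μ, friction γ = 1 ps⁻¹ and T = 300 K by default,
matching the conventional steered-MD thermostat settings. Units are Å, ps,
Da and kJ/mol; the conversion 1 kJ/mol = 100 Da Å² ps⁻² makes the system
consistent, so μ in these units is 100/(m γ). At T = 0 the noise term is
exactly zero and the integrator is plain gradient descent. An explicit
per-step check errors out when the deterministic displacement of any bead
reaches the smallest steric exclusion radius — the signature of a time step
too large for the stiffest interaction present.

Three guiding forces act between mass-weighted centroids, each a
zero-rest-length harmonic (U = ½ k d², pulling force k·d — the natural
reading of a distance-dependent force with units kJ mol⁻¹ Å⁻²; constant
force pulling is rejected on those units):

* 0.2 kJ mol⁻¹ Å⁻² between the cofactor methyl group and the catalytic
  lysine nitrogen,
* 0.1 between the adenine-ring triad and a receptor anchor triad,
* 0.05 between the amino-acid-moiety triad and a second anchor triad.

The receptor is rigid scaffolding: reaction forces on it are discarded.
Excluded volume is a purely repulsive linear spring between bead–atom pairs
inside the sum of their radii (k_rep = 6 kJ mol⁻¹ Å⁻² in the default toy
system — soft enough that thermal force spikes stay far from the step-size
check, hard enough that thermal penetration, √(kBT/k_rep) ≈ 0.6 Å, cannot
cross the ~2.7 Å repulsive zone of the pocket wall). Ligand beads are
bonded by harmonic springs (k = 10 kJ mol⁻¹ Å⁻², rest lengths from the
construction geometry); three cross-bonds stiffen the methyl–sulfur
orientation so the docked pose keeps near-linear Nε–C–S geometry.

The default toy system places an 8-bead cofactor (methyl carbon, sulfur,
and two three-bead triads) 27 Å along the pocket axis from a spherical
6 Å pocket with a 55° mouth; the catalytic nitrogen sits at the pocket
centre with the Cδ direction at 109° to the axis, so the axial approach
realizes the TS geometry by construction. The *occluded* variant seals the
mouth with one wide gate sphere whose surface swallows the mouth rim. The
two anchor triads are non-steric marker sites placed exactly at the docked
resting positions of their ligand triads, so the weaker guide forces vanish
(and exert no net torque) in the bound pose; with the asymmetric force
constants 0.1/0.05 any other placement systematically tilts the bound
ligand. Bead masses are a uniform 150 Da — coarse beads standing for atom
groups, chosen so that diffusive exploration and steered drift are balanced
at 300 K and the stability check sits ~7 standard deviations above thermal
force fluctuations.

Default integration: Δt = 0.02 ps, 5000 steps (100 ps), recording every 50
steps (1 ps, 101 frames including the initial one). With the combined
steering constant ≈ 0.35 kJ mol⁻¹ Å⁻² and total ligand mass 1200 Da the
approach time constant is ≈ 34 ps, so 100 ps ≈ 3 time constants suffices
for the open pocket to dock deterministically, while at 300 K individual
replicates may or may not thread the mouth — exactly the per-replicate
variability the success-count statistics are built for. Replicate i of an
ensemble runs with seed `base_seed + i` on R's default Mersenne-Twister
generator; identical inputs give bit-identical trajectories.

What the toy emulates: the shape of the computation — seeded replicate
ensembles, frame recording, centroid steering, steric gating of an
association channel. What it does not emulate: force-field energetics,
solvent, electrostatics, internal receptor flexibility, or realistic
association kinetics. Passing tests therefore certify the analysis
machinery, not any biological rate.

## Pocket volumetrics

The pocket measure re-implements the POVME-style grid algorithm with each
stage's semantics fixed explicitly (the published parameter set names the
stages but not their internals, so the package documents its own
interpretation and validates it against brute-force oracles):

1. **Inclusion grid** — an axis-aligned lattice (default 0.4 Å spacing)
   anchored at the first inclusion-sphere centre; points inside at least
   one closed inclusion sphere are kept, in deterministic lexicographic
   order. Anchoring at a sphere centre makes results independent of point
   ordering and input permutation.
2. **Proximity pruning** — drop points within `distance_cut` (default
   0.4 Å) of a receptor heavy-atom centre (`center` mode), or within
   `vdw_radius + distance_cut` (`vdw` mode; radii C 1.70, N 1.55, O 1.52,
   S 1.80 Å). `vdw` is the realistic default; `center` mode exists so the
   analytic hollow-shell oracle is exact. Whether the published 0.4 Å cut
   is measured to centres or to van der Waals surfaces is not stated
   anywhere authoritative, hence both modes.
3. **Convex-hull exclusion** (default on) — keep points inside or on the
   convex hull of the receptor heavy atoms. The hull is built by an
   incremental triangulation (no 3-D hull package ships with the
   environment's R), and membership is a half-space test with a 1e-7 Å
   boundary tolerance.
4. **Contiguity filter** — iteratively delete points with fewer than
   `contiguity_criterion` (default 3) neighbors in their 26-neighborhood
   until a fixed point, then keep only connected components containing the
   lattice point nearest an inclusion-sphere centre. When that snapped
   point was itself pruned (common when an atom sits on the sphere centre),
   the nearest surviving point within that sphere seeds instead — a
   deterministic fallback that keeps the measure well-defined.

Volume = surviving points × spacing³, always bounded by the inclusion-region
volume, and each stage is a subset operation. Volumes are binned into
right-open bands with edges 0, 25, 70 Å³ (the last band unbounded), frames
are subsampled at 10% in seeded triplicates, and conditions are compared by
the ≥ 70 Å³ fold enrichment plus an equal-variance t-test over the
triplicate large-volume fractions. A zero reference fraction reports an
infinite fold with a warning rather than an error.

## Contact occupancy

Contacts follow a pure distance rule: two groups are in contact in a frame
when any heavy-atom pair is strictly below 4.5 Å. No angular hydrogen-bond
criterion is added — a hydroxyl-to-backbone "H-bond" readout is emulated by
restricting the groups to the hydroxyl oxygen and backbone nitrogen. The
per-replicate occupancy fraction (not the pooled frame count) is the
statistical unit handed to the t-test; the pooled reduction is also
computable but per-replicate is the default, since replicate means are what
the replicate-based t-test assumes.

## Statistics

* `ttest_equal_var_two_tailed` — pooled-variance Student t with
  df = n₁+n₂−2 and symmetric two-tailed p. A pooled variance of exactly
  zero is undefined; the documented convention is t = 0, p = 1 for equal
  means and t = ±Inf, p = 0 otherwise.
* `binomial_upper_tail` / `binomial_lower_tail` — exact tails satisfying
  the complement identity.
* `compare_success_counts` — the spreadsheet-style binomial construction is
  under-specified in the field (tail direction, choice of null rate), so
  the construction is selectable and always reported with the number. The
  default is the upper tail of the alternative count under the reference
  condition's empirical rate — the minimal construction that tests "more
  successes than expected" — with a 1/(2 n_ref) floor (and warning) when
  the reference count is zero.

## Numerical choices and edge cases

* Distance criterion strict, angle windows closed; angle computation clamps
  the cosine into [−1, 1] before `acos`.
* Kabsch superposition requires ≥ 3 non-collinear fit atoms (second
  singular value > 1e-8 relative) and always returns a proper rotation.
* PDB output errors on |coordinate| ≥ 10⁵ Å (column overflow); readers
  error on MODEL atom-count mismatches (naming the model) and unparsable
  coordinates (naming the line), and skip altloc records other than ''/'A'
  with a warning.
* Element masses come from a small embedded table (H, C, N, O, S, P);
  unknown elements get 12.0 Da with a warning. Hydrogens are retained in
  the data model — steering centroids legitimately include them — and
  heavy-atom filtering applies only where a rule says "heavy atoms".
* Lattice keys are encoded as integers in a base large enough to avoid
  collisions, keeping the contiguity filter exact.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at
deliberately desk-scale sizes chosen as the package's own defaults: 100
replicates per condition × 5000 steps of the 8-bead toy system (≈ 100 ps
each), 10,000-geometry detector sweeps, grids of a few thousand points, and
hollow shells of ~2800 atoms. These sizes keep a complete validation run in
the minutes range on one CPU while leaving every statistical mechanism
(binomial counting, triplicate subsampling, per-replicate t-tests)
exercised at full protocol fidelity.

## Known limitations

* The simulator is overdamped and coarse: no inertial dynamics, no
  solvent, rigid receptor. It discriminates open from occluded pockets; it
  does not predict rates or affinities.
* The contiguity filter is one defensible reading of a "contiguous points
  criterion"; other POVME-compatible readings exist.
* Published inclusion-sphere coordinates are frame-specific to whatever
  prepared model they came from; the package treats them purely as
  configuration inputs and offers no automatic transfer between structures.
* Binary trajectory formats (DCD/XTC), topologies, bond perception and
  protonation logic are out of scope; PDB/XYZ cover the intended use.
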