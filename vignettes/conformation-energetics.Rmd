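---
title: "Coarse-grained conformation energetics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained conformation energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgconform)
```

## The problem

Surfactant-based drug vehicles such as the paclitaxel/Cremophor EL/ethanol
micelle owe their behaviour to the conformational states of their
components: the drug's flexible phenyl side chains around a rigid fused-ring
core, and the surfactant's three PEG-headed wings that fold, spread or
spiral.  `cgconform` quantifies those states.  Its pipeline is: map
all-atom structures to coarse-grained (CG) bead networks, derive a bonded
topology from a conformational ensemble, minimize each isolated conformer
under the resulting potential, and compare conformers through relative
energies and shape descriptors.

## Units and conventions

Everything internal is in GROMACS units: nm, amu, kJ mol⁻¹, e, ns.  PDB
files are the single Angstrom boundary (converted on read/write);
intramolecular shape descriptors are *reported* in Angstrom because that is
the customary unit for ring separations.  Angles are accepted and reported
in degrees, converted to radians internally.  All indices are 1-based — in
R, as in the GRO and ITP file formats themselves, so no boundary conversion
exists anywhere in the package.

Two geometric conventions deserve note:

* **Angles** are measured at the central bead between the two flanking
  beads, so a straight chain reads 180°.  A chain-vector convention (angle
  between successive bond vectors, 0° for a straight chain) also appears in
  the literature; the two are related by θ′ = 180° − θ.  The central-bead
  convention is the one presupposed by the harmonic and G96 angle
  potentials, so it is used throughout.
* **Dihedrals** follow the `atan2` form with 0° = *cis* and range
  (−180°, 180°].  The test suite validates it against an independent
  rotation-construction oracle (place the fourth particle by explicitly
  rotating a cis-built reference about the central bond) to < 1e-9°.

## Mapping and topology derivation

`map_frame()` places each bead at the mass-weighted mean of its member
atoms.  Because a weighted mean of weighted means with conserved weights is
again the overall weighted mean, per-molecule centres of mass are conserved
to machine precision — an invariant the tests assert directly.

`derive_topology()` averages measured internal coordinates over all
molecules and frames.  Dihedral averages are *circular* means: records at
{+179°, −179°} must average to 180°, not 0°.  Equilibrium values are all
the data can determine; force constants are not derivable from means, so
they are either (a) fixed, config-supplied defaults — 1250 kJ mol⁻¹ nm⁻²
for bonds, 25 kJ mol⁻¹ for angles, 5 kJ mol⁻¹ for dihedrals, magnitudes
typical of MARTINI-class force fields — or (b) obtained by Boltzmann
inversion `k = k_B T / var` when the ensemble is a thermal sample.  For
periodic dihedrals the small-oscillation correspondence gives
`k_φ = k_B T/(n² var)`, with the phase chosen so the potential minimum sits
at the circular mean.  Inversion of a zero-variance coordinate is refused
with a pointer to fixed-k mode rather than silently returning infinity.

When a periodic box is present, every displacement used in an internal
coordinate is minimum-imaged, so molecules spanning a box face do not
corrupt the averages.

## The energy model

Bonded forms: harmonic bonds ½k_b(r−b₀)²; angles either harmonic
½k_θ(θ−θ₀)² (θ in radians internally) or G96 ½k_θ(cosθ−cosθ₀)²; dihedrals
either periodic k_φ(1+cos(nφ−φ₀)) or Ryckaert–Bellemans
ΣₙCₙcosⁿ(φ−180°).  Nonbonded: Lennard-Jones and Coulomb, truncated at a
cutoff (default 1.0 nm) with an optional potential shift so V(r_c) = 0 —
the shift removes the energy discontinuity at the cutoff, which is what
matters for minimization.  No Ewald summation is implemented: the
package's energy comparisons are intramolecular, single-molecule-in-a-box
calculations where long-range electrostatics beyond the cutoff has no
role; this is a deliberate scope decision, not an approximation of a
planned feature.

Mixing rules: geometric (`√(εᵢεⱼ)`, `√(σᵢσⱼ)`) by default, Lorentz–Berthelot
selectable.  Both conventions are current in CG and AA force fields
respectively, so the choice is surfaced as configuration rather than
hard-coded.  Exclusions default to bonded separations 1–2 and 1–3, with
1–4 pairs included and scalable by `fudge_lj`/`fudge_qq` (default 1.0,
i.e. unscaled, the CG convention; AA force fields would set their own
factors).

Every term has an analytic gradient, validated in the tests against
central-difference differentiation of the energy at tolerance 1e-4
relative for random small systems — bond, both angle forms, both dihedral
forms, LJ and Coulomb.

## Minimization and relative energies

`minimize()` is adaptive steepest descent: trial step along the force
direction scaled so the largest-force particle moves by the current step
size; accepted (downhill) steps grow the step ×1.2, rejected steps shrink
it ×0.5 and retry.  Accepted energies are therefore non-increasing by
construction, and convergence is declared when the maximum per-particle
force drops below `fmax` (default 100 kJ mol⁻¹ nm⁻¹, the conventional
pre-MD relaxation target).  An input already below the threshold is
returned unchanged with zero steps.  The default threshold is a
*relaxation* criterion; tests that need the analytic minimum of a single
bond to 1e-4 nm tighten `fmax` accordingly (k_b·1e-4 ≈ 0.1 kJ mol⁻¹ nm⁻¹).

Potential energy is gauge dependent — adding a constant to any term moves
every U equally — so `relative_conformation_energies()` reports
ΔU = U − U^ref with U^ref the ensemble minimum, after centring each
conformer in a common box and minimizing it in isolation.  ΔU ≥ 0 with
min ΔU = 0 by construction, and the tests verify both gauge invariance
(an added constant leaves every ΔU unchanged) and rigid-motion invariance
of minimized energies (< 1e-6 kJ mol⁻¹ over random rotations and
translations).  Non-converged conformers are flagged, not dropped.

## Ensemble statistics and descriptors

`ensemble_statistics()` uses the population standard deviation (divisor
n, not n−1): on the bundled 32-conformer all-atom energy column this
reproduces the printed σ = 9.556 exactly, which a sample-sd convention
does not; the package treats that agreement as the definition fixed by
the reference data.  Medians for even n are the mean of the middle pair
(the bundled table's printed median 18.845 is that value, 18.8445,
rounded at the third decimal).  Histograms use half-open bins
[origin + k·w, origin + (k+1)·w); defaults of width 10 kJ mol⁻¹ from 0
suit drug-conformer energies, and width 100 kJ mol⁻¹ from 50 reproduces
the surfactant energy groupings ("50–150", "350–450", ...); both are
plain arguments.

Ring-centroid distances use mass-weighted centroids for consistency with
every other centre in the package; a geometric option exists because
centroid weighting is rarely stated in figure captions.  The conformation
radius R_C is the per-molecule mass-weighted radius of gyration about the
molecule's centre of mass — the centre is a choice (the alternative being
a geometric centre) and is documented as such.  `rmsd()` performs no
Kabsch superposition: the intended use is tracking drift against a fixed
reference in one box, where superposition would mask exactly the motion
being measured.

For aggregates of many molecules, `radius_of_gyration()` offers a second
centring mode — the mean of per-molecule centres of mass — matching the
grouped-aggregate procedure used for surfactant clusters, where each
molecule contributes equally to the group centre regardless of mass.

## Trajectory analyses

Partial density profiles divide per-slab mass by slab volume and average
over frames; the identity Σ(valueᵢ·slab volume) = mean selected mass holds
exactly for any input and is asserted as such.  The RDF uses the standard
shell-volume/partner-density normalization with the instantaneous box
volume per frame (NPT boxes fluctuate), minimum imaging, and self-pair
exclusion for overlapping selections.

MSD analysis first unwraps coordinates by accumulating minimum-image
steps between consecutive frames (a particle crossing a box face thus
produces a continuous track), then averages squared displacements over
all particles and all time origins within each analysis window — maximal
origin averaging, the standard practice when the estimator's variance
matters more than origin independence.  Each window gets a least-squares
line; the diffusion constant is slope/6 under the 3-D Einstein relation
(`einstein_3d`, default) or the raw slope (`raw_slope`) for
compatibility with analyses that fit MSD = D·t + c literally.  Both are
reported with R² so a non-diffusive (e.g. ballistic) regime is visible in
the fit quality.

## Formulation arithmetic

Molecular weights come from an embedded IUPAC standard-atomic-weight
table (5 significant figures).  Mole counts are reported both raw and
rounded to 1e-6 mol, the micro-mole presentation customary for recipe
tables; with the bundled masses this converts the classic 0.006 g drug /
0.5 ml surfactant (ρ = 1.05 g cm⁻³) recipe to 7e-6 and 212e-6 mol.
Ethanol's density is deliberately *not* embedded: the recipe literature
implies ρ ≈ 0.781 g cm⁻³ without stating it, so it remains a required
user input.  One known inconsistency in the reference data is surfaced
rather than hidden: the reported 765.447 nm³ ideal volume of 200
surfactant molecules implies MW ≈ 2420 g mol⁻¹, whereas the printed
formula C126H242O45 gives 2477 g mol⁻¹ (→ 783.5 nm³).  Downstream
expansion arithmetic therefore takes the molar volume as an *input*
(`aggregate_expansion(v_aggregate, v_molar)`) instead of recomputing it.

## Synthetic fixtures: what they emulate and what they do not

The generators produce the geometry classes the toolkit targets — a
57-bead three-winged surfactant (13 polar head + 6 apolar tail beads per
wing, wings joined at a triangular junction), a 24-bead rigid-core drug
with three labelled 3-bead rings, plain bead chains — with every bond at
exactly the requested length and small seeded kinks keeping angles and
dihedrals well-defined.  `sample_conformer_ensemble()` draws internal
coordinates independently from their Boltzmann marginals (Gaussian for
harmonic terms, rejection sampling for periodic dihedrals) and rebuilds
Cartesian coordinates by sequential NeRF placement with a canonical first
triad, removing rigid-body ambiguity from regression tests.
`brownian_trajectory()` takes Gaussian steps of per-axis variance 2DΔt
and retains the unwrapped truth alongside the wrapped frames.

These fixtures validate *estimators*, not physics: independent-marginal
sampling has no coupling between internal coordinates, Brownian particles
do not interact, and the toy molecules carry no chemistry.  A passing
test therefore certifies that mapping, inversion, MSD and RDF machinery
recover known inputs — it says nothing about force-field accuracy on real
molecules, which is out of scope for a desk-scale package.  Box assembly
reproduces the diagonal corner-to-corner layout with a 0.10 nm
inter-phase gap used to initialise strongly contrasted mixtures, and a
random-insertion mode with a minimum-distance rejection criterion.

All generators are pure functions of (spec, seed): the global RNG state
is saved and restored around each call, and identical seeds give
byte-identical output.

## Problem sizes and numerical tolerances

The statistical tests run at sizes chosen to make their tolerances
comfortable rather than marginal: Boltzmann-inversion recovery within 10%
at n = 10⁴ samples; Brownian diffusion recovery within 10% at 500
particles × 100 frames; ideal-gas RDF flat within 0.05 at 600 particles ×
15 frames (relative bin noise ≈ 0.4%); density flatness within 5% using
5 × 10⁴ particle configurations.  Oracle-equivalence checks (Rg, RMSD,
correlations, dihedrals) are deterministic and asserted at 1e-9–1e-12.
Degenerate geometry (collinear dihedral beads, zero-length angle arms,
coincident nonbonded particles) is an explicit error with an actionable
message, never a NaN.

## Known limitations

Orthorhombic boxes only; no binary trajectory formats (XTC/TRR/DCD); no
velocities; no improper dihedrals; no thermostats, barostats, constraint
algorithms or Ewald electrostatics — the package analyses and minimizes
configurations, it does not run dynamics.  RMSD offers no rotational
superposition.  The CG bead *types* are opaque labels: nonbonded
parameters are user-supplied configuration, not bundled force-field data.
The shape-descriptor set for three-winged surfactants (beyond energy,
radius and ring distances) is deliberately not guessed at; only
descriptors with unambiguous definitions are implemented.
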