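---
title: "Virtual implant therapy on a voxel-based mandibular FE model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual implant therapy on a voxel-based mandibular FE model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package models

`implantfem` simulates the mechanics of single-tooth implant therapy in the
posterior mandible. A CT-like voxel volume of a mandibular segment is turned
into a heterogeneous linear-elastic finite-element model; the first molar is
virtually extracted; one-piece titanium implants spanning a grid of three
diameters (3.8, 4.3, 6.0 mm) by four intrabony lengths (9, 11, 13, 16 mm)
are virtually placed into the grafted socket; each model is loaded with a
50 N occlusal force applied at a single node on the buccal cusp incline,
tilted 45° from the tooth axis toward the lingual side; and the equivalent
(von Mises) stress in the peri-implant bone is summarised per design.

The headline quantity is the maximum element-wise equivalent stress over
the peri-implant bone, reported per design together with its location
(neck/middle/apex third of the intrabony depth; buccal or lingual of the
implant axis). On the default synthetic phantom the sweep shows the
clinically expected pattern: peak stress concentrates at the crestal
(neck) bone on the loaded side and falls with increasing implant diameter
and, more weakly, with increasing length — the cantilever logic of an
osseointegrated implant, whose supracrestal lever arm is the same in every
design while the intrabony part stiffens with diameter.

## The constitutive model

Bone is heterogeneous, isotropic and linear elastic. Each element's
apparent density is derived from the CT number of its parent voxel,

ρ (gf/cc) = ct × 0.945 × 10⁻⁴,

with negative CT numbers clamped to zero (the calibration is undefined for
negative density; air and marrow spaces then enter with near-zero
stiffness). Young's modulus follows the three-branch power/linear law

* E = 0.001 MPa at ρ = 0,
* E = 33 900 ρ^2.20 for 0 < ρ ≤ 0.27,
* E = 5507 ρ + 469 for 0.27 < ρ < 0.6,
* E = 10 200 ρ^2.01 for ρ ≥ 0.6,

with ν = 0.4 for bone. Teeth are homogeneous (E = 4.80 × 10⁴ MPa,
ν = 0.23), implants are titanium (E = 11.0 × 10⁴ MPa, ν = 0.29). The
printed branches are implemented verbatim, including their mild
inconsistencies: the law is not globally monotone — the high branch starts
3.2% below the middle branch at ρ = 0.6, and the 0.001 MPa constant at
ρ = 0 exceeds the power branch for ρ < 3.8 × 10⁻⁴. We deliberately do not
smooth or floor the law; the tests record the measured boundary jumps
(+2.8% at 0.27, −3.2% at 0.6) instead. "Non-linear material properties"
here means *heterogeneous* coefficients inside a linear static solve; no
plasticity or contact is modelled, and the bone–implant interface is
perfectly bonded (complete osseointegration, shared mesh nodes).

## The synthetic phantom

No subject CT ships with the package, so the generator builds a
parametric mandibular segment: a curved rectangular-section prism
(arch radius 30 mm) of bone, 12.5 × 11.7 mm in cross-section and 21 mm
tall, wrapped in a 1.56 mm cortical shell (buccal/lingual surfaces,
inferior border and crest), with a molar-sized tooth (radius 4.5 mm,
9 mm root, 6 mm crown) on the ridge. Voxels are 0.39 mm isotropic.

CT numbers are expressed on the raw scanner scale the density calibration
expects, not on the Hounsfield scale: the calibration slope maps
ct = 14 000 to cortical density 1.32 gf/cc (E ≈ 18 GPa) and ct = 4800 to
trabecular density 0.45 gf/cc (E ≈ 3 GPa), which are the physiological
targets. Defaults are cortical 14 000 ± 700, trabecular 4800 ± 1600,
teeth 20 000 (noise-free). The trabecular spread deliberately populates
all three nonzero branches of the modulus law (the generator checks this
and warns otherwise).

The noise field is Gaussian with a 1.2 mm correlation length, implemented
by smoothing white noise with a variance-preserving Gaussian kernel. The
correlation length is a modelling statement, not a convenience: the
density-modulus calibration is defined for *apparent* (continuum-scale)
density, which varies smoothly over millimetres. Uncorrelated per-voxel
noise at 0.39 mm would instead emulate unresolved trabecular
microstructure — producing hundred-fold stiffness jumps between adjacent
elements and making the reported single-element stress maximum an
extreme-value statistic of the noise tail rather than a mechanical
quantity.

Phantom dimensions were chosen so that the mechanical environment of the
implant matches the clinical situation the model represents:

* the ridge is wide enough (11.7 mm) that even the 6.0 mm implant keeps a
  full trabecular/graft envelope laterally — its peri-implant element ring
  must not touch the buccal/lingual cortical plates, which would couple the
  readout to a material discontinuity;
* the socket is molar-sized, so the crestal element ring of *every*
  diameter lies in the same homogeneous socket graft and diameters are
  compared like for like;
* 21 mm of bone leaves a 3.5 mm apical safety margin below the longest
  (16 mm) implant, the usual clinical distance to the mandibular canal;
  with a tighter margin the apex bears against the stiff inferior cortex
  and apical stress can overtake the neck value.

What the phantom does **not** emulate: anatomical surface shape, multiple
rooted teeth, the mandibular canal, cortical thickness variation,
scanner physics (beam hardening, partial-volume blur at the shell), or
anisotropic bone. Passing trend tests on the phantom therefore shows that
the pipeline reproduces the *mechanics* of the diameter/length effect at
realistic stiffness contrasts — not that it predicts subject-specific
stress magnitudes, which depend on the individual anatomy.

## Segmentation, extraction and placement

Segmentation is plain two-threshold labelling (background / bone / tooth;
defaults 1200 and 17 500 on the raw CT scale). Threshold segmentation of a
noisy interior leaves a small fraction of sub-threshold "pore" voxels
enclosed in bone; `fill_enclosed_pores()` relabels them as bone while
keeping their low CT (hence near-zero stiffness), the automated analogue
of correcting imperfect threshold regions by hand before model
construction.

Virtual extraction removes the target tooth: supra-crestal crown voxels
revert to background, sub-crestal root voxels become bone whose CT is the
mean of trabecular bone within a 2 mm shell around the socket — the
extraction space "healed" with bone before placement. Cortical-level CT
values (≥ 9000 by default) are excluded from the fill estimate.

The implant solid is a smooth cylinder with a hemispherical apex reaching
the specified length below the crest, continued above the crest by an
abutment cylinder and a 7 × 7 × 3 mm crown block; the supracrestal height
(8 mm default) is identical across all designs. Voxelisation uses a
2 × 2 × 2 partial-volume majority rule: a voxel joins the solid when at
least half its subsampled interior lies inside the continuous solid.
Plain centre-membership leaves single-voxel stair-step protrusions on the
cylinder surface which act as artificial stress concentrators on the
element-wise maximum. The load target is the buccal corner of the crown
top face (2.5 mm buccal of the axis); the actual load node is the nearest
implant node, lowest id on ties.

## Discretisation and solver

The labelled volume is meshed by splitting each voxel into five
tetrahedra, mirror-alternated in a 3D checkerboard so neighbouring voxels
share their face diagonals and the mesh conforms. Nodes are merged exactly
on the voxel lattice (integer keys — no tolerance needed). Elements are
4-node constant-strain tetrahedra with exact one-point integration; per
element E, ν come from the constitutive table, with element density
inherited from the parent voxel.

The global system (three DOF per node; ~186 000 DOF for the default
phantom) is assembled in triplet form (upper triangle) and solved with a
CHOLMOD supernodal sparse Cholesky factorisation after eliminating the
clamped DOFs — every node within one voxel layer of the inferior border
is fully fixed, the discrete reading of a completely fixed inferior
mandibular border. Above 3 × 10⁵ DOF the solver switches to
Jacobi-preconditioned conjugate gradients at 10⁻⁸ relative tolerance.
Every solve verifies a residual below 10⁻⁶ (typically 10⁻¹²) and reports
the equilibrium gap |Σ reactions + applied load|, which the tests bound
by 10⁻⁶ N. Stress is recovered per element through the constant-strain
operator; the equivalent stress is the standard von Mises invariant, and
principal stresses are the ordered tensor eigenvalues.

The point load is applied literally at one node, accepting the local
singularity; the reported maxima are taken over *bone* elements adjacent
to the implant (node-sharing one-ring), far from the loaded crown node,
so the singularity cannot contaminate the headline metric. Maxima are
element-wise and unaveraged — nodal averaging schemes are solver-specific
and would blur the comparison.

## Verification

Three independent checks anchor the solver (all in the test suite):

* **Patch/bar test** — a uniaxially loaded rectangular bar with consistent
  end tractions reproduces the uniform stress F/A to 10⁻⁸ relative
  accuracy (the linear solution is in the CST function space, so this is
  exact up to round-off).
* **Cantilever bending** — an 8 × 8 × 80 voxel beam under end shear
  deflects within 5% of the Euler–Bernoulli closed form F L³/(3EI)
  (measured −2.9%; constant-strain tets converge from the stiff side, and
  8 elements through the section at slenderness 10 is the refinement that
  reaches the 5% band).
* **Dense oracle** — on meshes below 300 DOF the sparse path agrees with a
  dense brute-force assembly and `solve()` to 10⁻⁸.

Element stiffness itself is validated against numerical differentiation of
the strain-energy functional, and the usual structure checks (symmetry,
six-dimensional rigid-body nullspace, linearity in the load, invariance of
stresses under global stiffness scaling, rotation invariance of the von
Mises invariant) are property-tested.

## Numerical choices and degenerate inputs

* Node merge needs no tolerance (exact lattice keys); mesh volume equals
  voxel volume to 10⁻¹⁰ relative.
* Branch boundaries of the modulus law follow the printed inequalities
  (0.27 in the low branch, 0.6 in the high branch).
* Ties in node/element selection resolve to the lowest id.
* Sub-threshold pores *inside* the implant solid are displaced by the
  implant; placement fails only when more than 5% of the intrabony solid
  lies outside bone (lateral exit), or when the apex would enter the
  inferior cortical shell (reported with the overshoot in mm).
* Zero-noise phantoms are legal (every cortical voxel takes exactly the
  class mean) but cannot populate all modulus branches; the generator then
  warns rather than fails.
* All randomness flows from the single phantom seed; identical
  configuration and seed reproduce the stress summary byte-for-byte.

## Problem sizes

The default phantom (32 × 34 × 76 voxels) meshes to ~300 000 tetrahedra /
~186 000 DOF per configuration; the full 12-design sweep solves twelve such
systems, which is the package's reference experiment. The test suite runs
the same sweep once plus a battery of small verification problems (the
largest is the 24 000-DOF cantilever). Scaled-down phantoms used in unit
tests keep every geometric feature (shell, tooth, graft, supracrestal
block) at 1/2 linear scale.

## Known limitations

* Stress magnitudes are phantom-specific; only their ordering and location
  are designed to be robust. Subject CTs will produce different absolute
  values.
* Voxel meshes cannot represent threads or smooth fillets; thread-level
  micro-mechanics is out of scope.
* The single-node load is a deliberate idealisation; moving the readout
  closer than one element ring to the load would expose the singularity.
* DICOM support covers single-frame explicit-VR little-endian CT series
  with isotropic spacing — enough to import research exports, not a
  general DICOM stack.
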