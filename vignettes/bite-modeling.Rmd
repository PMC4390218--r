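---
title: "Finite-element bite modeling and cross-specimen scaling with biteFEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-element bite modeling and cross-specimen scaling with biteFEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biteFEM)
```

## The problem

When an animal bites, the jaw-closing muscles press the skull against the
prey, and the skull's bony architecture decides where that load is carried
and where stress concentrates. For taxa that cannot be instrumented in
vivo — including giant salamanders, whose broad flat skulls lack the bony
bridge between the posterior maxilla and the jaw-joint region that most
forceful biters possess — a static finite-element model of the skull under
muscle loading is the standard way to ask: how does the bite position
(anterior versus posterior tooth row, one side versus both) change the
stress field, and how do specimens of different size compare under
equivalent loads?

biteFEM implements that workflow end to end on tetrahedral meshes: muscle
definitions become distributed surface tractions, a linear-elastic static
problem is solved under prehension/joint/occipital constraints, Von Mises
stress fields and bite forces (as constraint reactions) are extracted, and
quasi-homothetic scaling laws make loads comparable across specimens.

## Model and assumptions

**Material.** Bone is modelled as linear, elastic, homogeneous and
isotropic, with defaults E = 6650 MPa and Poisson's ratio 0.35
(crocodylian cortical-bone values commonly borrowed for anamniotes whose
bone properties are unmeasured). Two consequences matter for
interpretation: absolute displacements are not trustworthy when E is
borrowed, but the *stress distribution* of a statically determinate-in-
the-large problem is insensitive to E; and for a homogeneous isotropic
body the stress field scales linearly in the applied loads, which is what
makes the cross-specimen scaling laws exact statements rather than
approximations.

**Units.** Everything is in the consistent mm–MPa–N system (1 MPa over
1 mm² gives 1 N). Meshes carry a units tag that is validated, never
converted.

**Elements.** Linear (4-node) and quadratic (10-node) tetrahedra, with
quadratic the default for analyses (linear kept for fast verification
runs). Quadratic elements are affine: mid-edge nodes sit at edge midpoints
at construction (an enforced invariant), so the Jacobian is constant and
the 4-point Gauss rule integrates the stiffness exactly. Stiffness uses
the Lamé-constant block form; constraints are imposed by elimination
(reduction to free degrees of freedom) rather than penalty, so reactions
are exact by back-substitution — deliberate, because the bite force *is* a
reaction. The reduced system is solved by sparse Cholesky factorization
(a direct method; with the mesh sizes used here an iterative fallback has
not been needed).

**Muscle loading.** Each jaw adductor (AME, the externus, on the
anterolateral roof; AMI, the internus, spread over the medial roof) is a
uniform contraction pressure P over its insertion patch — the constant-
PCSA assumption — directed along the line from the patch's area-weighted
centroid to its insertion point on the mandible. Nodal forces use the
consistent lumping for a uniform traction: equal thirds per corner on
linear faces; on straight-edge quadratic faces one third per mid-edge node
and nothing on corners. The resultant is exactly P·SM·d (SM the insertion
area, d the unit direction), and the adult default P = 0.3 MPa with
SM = 559.23 mm² reproduces the tabulated adult AME force of 167.77 N.

**Gape.** Gape is skull elevation plus mandible depression. Elevation
rotates the whole loaded skull rigidly; with constraints expressed in the
skull frame it cannot change the elastic problem, so it is recorded in
provenance and applied as a no-op. Mandible depression rotates the muscle
direction about the mediolateral (+z) axis in the opening sense. The
rotation is applied to the unit direction vector; a free vector is
unchanged by where the rotation axis is anchored, so the jaw-joint centre
does not enter (this also keeps the two study gapes, 6°/0° and 6°/15°,
exactly comparable: total load magnitude is gape-invariant).

**Constraints.** Prehension (bite contact) patches are fixed in all three
directions — the model of prey contact — while the jaw joints (quadrates)
are fixed dorsoventrally (y) and the double-headed occipital condyles
anteroposteriorly (x). In unilateral cases only the biting side's
prehension patch is constrained; muscles on *both* sides remain active,
because asymmetric biting is an asymmetry of prey contact, not of muscle
recruitment.

**Outputs.** Per-element Voigt stresses averaged over quadrature points,
nodal stresses by volume-weighted averaging of adjacent elements, Von
Mises equivalents of both, bite force as the resultant prehension
reaction (magnitude plus per-axis components and per-side split), and a
per-role reaction breakdown that closes the global force balance to
round-off.

## Scaling laws

To compare specimens that differ in size under "equivalent" loads, the
reference pressures are rescaled rather than the geometry. With body
volumes V, enclosing surfaces S and insertion areas SM for reference and
target:

* volume method (two-thirds power law):
  P_tgt = P_ref · (SM_ref/SM_tgt) · (V_tgt/V_ref)^{2/3}, equivalently
  F_tgt = F_ref · (V_tgt/V_ref)^{2/3};
* surface method: P_tgt = P_ref · (SM_ref/SM_tgt) · (S_tgt/S_ref).

The volume law is exact in the following sense: if the target body is a
homothety of the reference with linear ratio α = (V_tgt/V_ref)^{1/3} and
forces are scaled by α², the Von Mises field at corresponding points is
identical. This is both a theorem of linear elasticity and a property the
finite-element discretisation inherits exactly (stiffness scales as α,
loads as α², displacements as α, strains and stresses as 1), which is why
the test suite can assert it at 10⁻⁶ relative rather than at a
discretisation tolerance.

```{r scaling}
s <- scaling_inputs(V_ref = 144340, V_tgt = 24964,
                    SM_ref = 559.23, SM_tgt = 122.11)
scale_pressure_volume(0.3, s)                      # subadult AME pressure
scale_force_volume(0.3 * 559.23, 144340, 24964)    # subadult AME force
```

A note on printed precision: recomputing the published subadult table
from these formulas reproduces every entry at its printed precision
except two that were evidently truncated rather than rounded (the
volume-scaled AME pressure, 0.4265, printed as 0.42; and the area-scaled
AMI force, 156.445, printed as 156.44). biteFEM reports the computed
values.

## The synthetic specimens

CT-derived skull meshes are rarely redistributable, so the package ships
deterministic generators instead of data.

`make_patch_cube()` and `make_cantilever()` are the verification
geometries: the cube carries the uniaxial patch test (a uniform-stress
state every convergent element must reproduce exactly), the beam the
Timoshenko tip-deflection benchmark.

`make_skull()` emulates the features of a flat, broad salamander-like
skull that drive the load-path question, without claiming anatomical
fidelity: a dorsoventrally flattened dome shell over an elliptical
footprint (default 180 × 180 × 54 mm, a caricature of "flat and broad" at
adult giant-salamander scale; skull lengths are published but widths and
heights are not, so the 2:2:0.6 proportion is a package choice); a
posteromedial opening standing in for the interpterygoid vacuities, which
leaves the posterolateral rim as a suspended maxilla-like strip anchored
only at its anterior end; and an optional posterolateral gap
(`lateral_gap`, default TRUE) that removes the strip's bridge to the
quadrate region. Patches are selected by bands in the footprint's
normalised polar coordinates; the default bands put the AME/AMI
insertion-area ratio near the adult value 559.23/2333 ≈ 0.24 at the
default resolution. The mesh is built as a mirrored half-grid, so node
set, connectivity and patches are *exactly* symmetric under z → −z:
bilateral cases then produce mirror-symmetric solutions to solver
round-off, and left/right disjointness of paired patches is guaranteed
(faces touching the midline belong to neither side).

What the fixture deliberately reproduces: the suspension of the posterior
bite point, so that a posterior bite must route its reaction forward
through the preorbital roof — on the gapped fixture the posterior-bite
preorbital mean Von Mises exceeds the anterior-bite one by a wide margin,
the direction reported for the real skulls. What it does not reproduce:
real cortical thickness variation, sutures (also absent from the original
models), orbit fenestrae, tooth rows, or any quantitative stress value —
so passing tests validate the *mechanics and bookkeeping* of the
pipeline, and directional/qualitative statements about load paths, but
never numeric stress or bite-force levels of real skulls. Published bite
forces from the CT-based models are therefore not comparison targets
here.

Generator determinism: meshes are pure functions of their parameters;
the optional node jitter (off by default) touches interior nodes only,
under an explicit seed, so patch geometry and areas are reproducible by
construction.

## The case matrix

```{r matrix, eval = FALSE}
adult <- make_skull(skull_params(resolution = 9))
subadult <- make_skull(skull_params(length = 90, width = 90, height = 27,
                                    shell_thickness = 4.5, resolution = 4.5))
res <- run_matrix(adult, subadult,
                  list(material = material(), pressure = 0.3,
                       gape = gape_spec(6, 0), scaling = "volume"),
                  out_dir = "runs")
res$A
```

`run_matrix()` reproduces the eight-case study design — bilateral and
unilateral prehension × anterior and posterior bite position × reference
(nominal pressures) and target (scaled pressures) specimen — assembling
each mesh's stiffness once and reusing it across its four constraint
patterns. Cases are labelled A–H in that order. Per-case VTK fields
(displacements, nodal and element Von Mises) and a CSV summary are
written when `out_dir` is given; `compare_results()` forms the
cross-specimen ratios the scaling laws exist for. The default subadult
fixture is an isometric (half-scale) variant — a deliberate choice: with
an isometric pair the volume law predicts stress ratios of exactly 1, so
any deviation is a pipeline defect, not biology.

## Numerical choices and degenerate inputs

* Element orientation: construction repairs inverted tetrahedra by a
  vertex swap (with a count message); degenerate (zero-volume) elements
  are errors naming the element.
* Boundary bookkeeping: patches may only contain boundary faces; this and
  the mid-edge-midpoint invariant are checked by `validate_mesh()`.
* Quadrature: 1-point for linear, 4-point Gauss for quadratic tetrahedra —
  exact for the affine geometry used; stresses are sampled at the same
  points.
* Singular systems: constraint sets removing fewer than six degrees of
  freedom are rejected up front; a factorization that detects remaining
  rigid-body modes (e.g. all constrained nodes collinear) is reported as
  such rather than returning garbage.
* Homogeneous constraints only: duplicate (node, axis) entries across
  constraint roles are merged — with zero prescribed displacement they
  cannot conflict.
* Incompressibility: Poisson's ratio within 10⁻⁶ of 0.5 is an error (the
  constitutive matrix diverges); mixed formulations are out of scope.
* Empty patches: area 0 with a warning; an empty patch as a traction
  carrier or constraint site is an error.

## Verification summary

The test suite establishes, among others: exact (10⁻⁹) uniaxial patch
tests for both element orders; element stiffness against an independent
B-matrix oracle and dense assembly against a scatter oracle; Von Mises
against a principal-stress eigendecomposition on random tensors (10⁻¹²);
cantilever tip deflection within 2% of the Timoshenko closed form with
quadratic elements at four elements through the thickness, with
monotonically decreasing error under refinement for linear elements;
global equilibrium closure and reaction bookkeeping at 10⁻⁸ relative in
every solved case; exact homothety invariance of the Von Mises field at
10⁻⁶; and linearity (doubling pressures doubles stresses and bite
forces). Problem sizes were chosen to keep the full suite around a
minute: verification cubes at 2³ divisions, the Timoshenko beam at
20×4×4 quadratic, and skull fixtures at 9–12 mm resolution (about 3 700
quadratic tetrahedra, 24 000 degrees of freedom for the adult default) —
small enough to iterate on, large enough that the shell mechanics are
resolved.

## Limitations

Beyond the synthetic-geometry caveats above: the solver is linear static
(no contact, no large deformation, no dynamics or multibody jaw
mechanics); bone is isotropic and homogeneous (no orthotropy, no suture
compliance); muscle forces are uniform pressures along a single line of
action (no fibre architecture, no activation dynamics, and the small
adductor mandibulae posterior is not modelled); and bite-force magnitudes
from constraint reactions depend on the prehension patch extent, so they
are comparable within a fixture family but are not predictions for real
animals.
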