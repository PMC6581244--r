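---
title: "Methods: finite-element analysis of the developing infant femur"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finite-element analysis of the developing infant femur}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

The infant femur is only partly mineralised: the proximal epiphysis is
largely cartilage, invisible to CT-based bone models, and ossifies from a
centre that becomes the femoral head. `infantfem` implements a complete,
testable pipeline for asking how that non-ossified region changes the
mechanical response of the shaft: a parametric voxel phantom of the infant
femur, quadratic tetrahedral meshing, CT-style intensity-to-modulus mapping,
static solves under torsion and uniaxial loads, and a principal-strain
moment-to-fail of the diaphysis.

Everything runs on synthetic phantoms because the post-mortem images such
studies use cannot be shared. The phantom is not a stand-in visualisation:
it is the study condition, built to match the published morphometry of two
subjects (4 and 7 months) — proximal–distal lengths 10.55 / 13.28 cm,
proximal epiphysis volumes 1.24 / 7.91 cm^3 (a 6.4-fold difference), total
bone volumes 13.13 / 30.79 cm^3 — while everything those measurements do not
constrain is an explicit, documented parameter.

## The synthetic femur

`femur_params()` describes the phantom; `femur_preset("4mo")` and
`femur_preset("7mo")` encode the two subjects.

* **Geometry.** The diaphysis is a hollow cylinder (cortical shell around a
  trabecular core) with a mild oblique bow; the proximal epiphysis is the
  proximal half of an ellipsoid cut at the metaphyseal plane, tilted by the
  neck-shaft angle (default 145°) and anteversion (default 30°). The
  half-ellipsoid volume is analytically $(2/3)\pi abc$, so a volume target
  is met exactly by isotropic scaling of the semi-axes, and the shaft radius
  is derived in closed form from the total-volume target. Presets use a
  cortical thickness of 2.0 / 2.4 mm — plausible infant values; the printed
  morphometry constrains only lengths and volumes.
* **Intensities.** Region HU values default to 1860 (cortical), 360
  (trabecular), 190 (epiphysis) and 100 for background — soft tissue, not
  air, because a post-mortem limb scan embeds the femur in tissue and the
  element-averaged modulus of surface elements is only meaningful against
  that background. A linear ramp of width 3 mm at the metaphyseal plane
  emulates the smooth mineralisation gradient seen in the source imaging;
  i.i.d. Gaussian noise (default sd 30 HU) is added to non-background
  voxels under a fixed seed.
* **Numerical care.** The metaphyseal cut plane and the distal end plane are
  snapped to voxel boundaries, and the bow sweeps both transverse grid
  directions; both choices remove voxelisation aliasing so that labelled
  volumes converge (halving the spacing moves any label volume by < 1%) and
  the epiphysis volumes land within a fraction of a percent of their
  targets.

What the phantom does **not** emulate: CT physics (beam hardening, point
spread, partial-volume blur), the metaphyseal flare and greater trochanter,
marrow heterogeneity, and real cortical thickness variation. Passing tests
on the phantom therefore validate the *machinery* (meshing, mapping,
solving, post-processing) and the qualitative mechanics of a soft epiphysis
on a stiff shaft — not subject-specific strain magnitudes, which depend on
real geometry.

## Meshing

`mesh_from_labels()` builds a conforming 10-node tetrahedral mesh by a
structured lattice method: cubic blocks of edge near `target_edge` are kept
when at least half their voxels are labelled, split into six Kuhn tetrahedra
(face-conforming across blocks), and promoted to quadratic with one shared
mid-edge node per edge (node order: corners then mid-edges of
(1,2),(2,3),(3,1),(1,4),(2,4),(3,4) — the C3D10/VTK convention). Element
regions come from the majority voxel label per block, ties favouring the
ossifying epiphysis. The contract is the post-conditions — mesh volume
within 3% of the labelled volume, strictly positive corner Jacobians,
region coverage — not the particular generator; `tet_mesh_box()` and
`tet_mesh_cylinder()` provide structured benchmark meshes, and
`read_mesh()`/`write_mesh()` exchange VTU and Abaqus INP (C3D10) files.

The cylinder generator area-matches its polygonal cross-section to the true
circle, which makes section constants second-order accurate and lets
closed-form circular-shaft solutions serve as references without geometric
bias dominating.

## Material mapping

`element_modulus()` implements the integrated-average convention: the
affine HU-to-density step ($\rho = a + b\,\mathrm{HU}$) and the power law
($E = c\,\rho^d$) are applied pointwise to the trilinearly interpolated
intensity field and then volume-averaged over each element (256 sample
points by default), with the clamp applied to the averaged value. The
alternative average-HU-then-map ordering is available as a flag for
sensitivity studies only.

The default coefficients ($a=0$, $b=0.001$ g/cm^3 per HU, $c=6850$ MPa,
$d=1.49$, clamp 460–20000 MPa) are a documented placeholder for a QCT
calibration convention; they were chosen once so that the preset phantoms
reproduce the modulus range reported for infant femora (cortical peak
16–18 GPa, ossifying region 0.46–0.60 GPa, with ~0.46 GPa as the lower
bound of the mapped field). All coefficients live in
`calibration_law()`.

For the ossifying region the small-strain modulus is converted to
compressible Neo-Hookean parameters of
$W = C_{10}(\bar I_1 - 3) + (1/D_1)(J-1)^2$ via

$$C_{10} = \frac{E}{4(1+\nu)}, \qquad D_1 = \frac{6(1-2\nu)}{E},$$

with $\nu = 0.20$ for cartilage-like tissue; the stored records satisfy
these relations to machine precision and round-trip back to $(E, \nu)$.
Bone uses $\nu = 0.3$, the standard cortical value. Poroelastic constants
(permeability 0.00455, void ratio 4.50) are carried per element; the
permeability value is interpreted in the package's consistent mm–N–s unit
system, i.e. mm^4/(N s), which corresponds to the typical order of
cartilage permeability (≈ 4.6 × 10⁻¹⁵ m^4/(N s)).

## Solvers

* **Linearised (default).** Small-strain isotropic elasticity assembled
  from analytic element stiffness (4-point degree-2 quadrature, exact for
  straight-sided quadratic tetrahedra; a 5-point rule is available) and
  solved by supernodal sparse Cholesky. Neo-Hookean records participate via
  their recovered $(E, \nu)$. Inhomogeneous Dirichlet data, per-component
  constraints, and rigid (kinematic) couplings are supported.
* **Hyperelastic.** Diaphysis elements stay linear; ossifying elements are
  assembled in total-Lagrangian form with the exact Neo-Hookean second
  Piola–Kirchhoff stress and a forward-difference consistent tangent,
  solved by Newton iteration (relative residual 1e-8, 30 iterations per
  step, 5 load increments by default). At small strain the two modes agree
  to about 0.1%.
* **Poroelastic (transient).** Biot consolidation with incompressible
  constituents on the Taylor-Hood-like pairing (quadratic displacements,
  linear corner-node pressures), backward Euler in time; the undrained
  instant is obtained from the incompressible limit, and with drained
  boundaries the solution approaches the drained static solve. Only
  elements with poroelastic records carry pressure; bone is impermeable.

Element strains are volume-averaged over quadrature points; principal
strains are sorted eigenvalues of the averaged tensor. This is deliberately
more robust (and slightly smoother) than nodal-extrapolated contour
extrema.

## Anatomical frame and load cases

`build_frame()` slices the diaphysis at 25% and 75% of its axial extent
and takes the X axis through the two cross-section centroids
(proximal → distal); Y is the medial hint orthogonalised against X and
Z = X × Y points anteriorly. The slab centroids use a smooth cosine window
rather than a hard slab, which makes the recovered axis insensitive to
which elements straddle the slab edge: on structured cylinder meshes the
axis is exact to machine precision and invariant under refinement. Using
two interior shaft sections minimises the parasitic bending that anatomical
asymmetry would induce under axial load (< 5% transverse-to-axial tip
deflection on a straight cylinder). "Axial extent" means the diaphysis
only; the epiphysis is excluded, since the sections belong to the shaft.

`make_load_case()` builds the four standard cases: torsion (2 kN·mm about
X through Point 1, the proximal ossification centre) and 200 N uniaxial
forces along X, Y or Z at Point 1, with the patch around Point 2 (distal
shaft axis) fully fixed. Point loads are distributed over all nodes within
a patch radius (default 3 mm) as the minimum-norm nodal force set that
reproduces the requested resultant exactly — for a disc-shaped patch this
coincides with the classical torsion traction. A true single-node load is
singular in elasticity, so some distribution rule is unavoidable; the
minimum-norm rule is the least-committal one.

## Failure criterion

`failure_criterion()` encodes elastic strain limits of 0.73% (tension) and
1.04% (compression) — adult cortical values used as a proxy because no
infant-specific limits exist — evaluated over the diaphysis only. In
linearised mode the moment-to-fail is the probe moment scaled by the first
limit reached, and is exactly independent of the probe magnitude;
`load_to_fail_hyperelastic()` brackets and bisects the load for the
nonlinear mode.

Two exclusions shape the diaphysis mask. One element layer adjacent to the
region interface is always dropped. Beyond that, an optional geometric
buffer (`boundary_buffer`, default 16 mm ≈ one shaft diameter in the
pipeline) removes diaphysis elements near the interface *and* near
loaded/fixed patches. The rationale is Saint-Venant's principle: within
about one diameter of the metaphysis or of a load patch the strain field
depends on how the load enters (and genuinely concentrates at the
transition — a real finding, reported separately via the transition-slab
profile in `epiphysis_effect_report()`), whereas the *shaft capacity*
should be a property of the section resultants. A layer-count exclusion
alone cannot treat the with-epiphysis and bone-only models comparably,
because their proximal load paths differ by construction.

`epiphysis_effect_report()` compares a with-epiphysis solution against a
bone-only model meshed from the same image with the epiphysis removed and
torque spread over the free proximal end face. On both presets the
diaphyseal failure-load ratio falls well inside 0.8–1.25 while the
transition slab shows a clear strain concentration — the soft head barely
changes what the mid-shaft feels, but the metaphysis does see elevated
strain.

## Verification battery and problem sizes

The test suite pins the solver to independent references, at sizes chosen
to keep a full run within a few minutes:

* element stiffness vs an independently coded composite-quadrature oracle
  (1e-12);
* rigid-body null modes, linear and quadratic patch tests on a distorted
  mesh (1e-10);
* cylinder torsion vs $\gamma = T\rho/(GJ)$, compared pointwise at element
  centroid radii: 0.23%, 0.04%, 0.014% over three refinements
  (monotone, final mesh ≈ 5.4k elements);
* cantilever tip deflection vs Timoshenko theory (shear coefficient
  $6(1+\nu)/(7+6\nu)$): within ~1.5%, the residual being fixed-end
  restraint absent from beam theory;
* Terzaghi consolidation (40-element column, 160 graded backward-Euler
  steps) vs the classical series at 20 time factors: max error ≈ 0.6%;
* degenerate-epiphysis limits: scaling the epiphysis stiffness by 1e±5
  reproduces a rigid-coupling oracle and a statically equivalent free-end
  oracle to ≈ 1e-5 and ≈ 3e-3 on a central-shaft mask two diameters from
  the interface, where Saint-Venant equivalence holds.

The whole-femur analyses use 0.8 mm voxels and a 2.5 mm target edge
(≈ 5.7k / 13.1k elements for the two presets; ≈ 29k / 66k degrees of
freedom), and the four-load-case pipeline completes in well under a minute
per preset on one CPU. Finer meshes (1.7 mm) are used where the printed
modulus ranges are evaluated, since the cortical peak requires elements
that fit inside the shell.

## Known limitations

* Linearised mode reports small-strain tensors; the torsional strain
  maxima of real infant femora can approach the finite-strain regime, which
  is why the hyperelastic mode exists, but large-strain plots should use
  it explicitly.
* The structured lattice mesh has a stair-stepped surface; surface strain
  concentrations at individual jagged elements are mesh artefacts, which is
  one more reason capacity is evaluated on masked element-averaged strains.
  All comparative statements (with vs without epiphysis, degenerate
  limits) share meshes or masks, so these artefacts cancel.
* Bone is isotropic linear elastic; anisotropy and strain-rate dependence
  are out of scope, as is any dynamic or contact analysis.
* The failure limits are adult values; capacities should be read as
  relative measures between models, not as infant injury thresholds.
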