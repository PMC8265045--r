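---
title: "Anatomical scaffolds: interpolation, fitting and material embedding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomical scaffolds: interpolation, fitting and material embedding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anatscaffold)
```

## The model

A scaffold is a finite-element mesh used as a material coordinate system
for an organ or whole body. Each element is a tri-cubic Hermite cube: along
every local direction ξᵢ ∈ [0,1] the field is interpolated by the four
cubic Hermite polynomials

* value at 0: 1 − 3ξ² + 2ξ³
* derivative at 0: ξ − 2ξ² + ξ³
* value at 1: 3ξ² − 2ξ³
* derivative at 1: −ξ² + ξ³

so a 3-D element's geometry is determined by eight parameter *slots* per
corner node: the position and its mixed partial derivatives
(value, d/dξ₁, d/dξ₂, d²/dξ₁dξ₂, d/dξ₃, d²/dξ₁dξ₃, d²/dξ₂dξ₃,
d³/dξ₁dξ₂dξ₃), in that canonical order. Lower-dimensional elements use the
leading 2 or 4 slots. Because neighbouring elements share nodes — and hence
share the derivative parameters — the interpolated geometry is C1 across
element faces wherever both elements select the same *derivative version*
of the shared nodes. Versions (alternative derivative sets, indexed from 1)
exist so that elements meeting at apices or branch points, where a single
smooth derivative cannot serve all sides, can each select their own;
`continuity_report()` checks C0 everywhere and C1 exactly where versions
agree.

A **material point** is an (element, ξ) address. Because fields are
interpolated from nodal parameters, evaluating the same material point in
the `reference` (generic) field and in a `fitted` (specimen) field yields
corresponding physical locations; this is the mechanism by which data from
differently-shaped specimens become comparable.

Units are mm throughout; coordinates are right-handed.

## Scaffold generators

Tubular organs (`build_tube()`, `make_colon()`) sweep a parameterized
cross-section along a centerline. The centerline polyline is interpolated
with natural cubic splines, re-sampled uniformly in arc length (or at
prescribed stations), and equipped with rotation-minimizing frames computed
by the double-reflection method — unlike Frenet frames these do not flip at
inflection points. The cross-section radius is

r(θ, s) = r₀ + Σᵢ tᵢ·cos²(π·Δθᵢ/wᵢ)·[|Δθᵢ| < wᵢ/2] + a·½(1 + sin(2πλs − π/2))·E(θ)

where the cos² windows are taenia-coli-like longitudinal thickenings
(C1 by construction), the sinusoidal term models haustral bulging with
amplitude `a` and `λ` waves per axial segment, and E(θ) is the product of
the complements of the taenia windows so the bulges live *between* the
bands. The haustral wavelength default is 0.5 waves/segment so that
consecutive node rings alternate through the bulge rather than sampling it
at a constant phase. Species presets fix only the topological counts as
anatomical facts (3/2/0 taeniae for human/pig/mouse; 4/2/3 pulmonary veins
for human/pig/rat); all metric values (radii, lengths, wall thicknesses)
are plausible defaults and freely overridable.

Nodal derivatives of swept tubes are taken analytically in the angular and
radial directions and by centered differences of ring positions axially;
since each node's parameters are shared by all elements using it, the
result is C1 regardless. Radial interpolation across multiple wall layers
(the body scaffold has a visceral core plus an outer layer) goes through a
monotone (Hyman) spline of the layer radii so the radial derivative is
single-valued at layer interfaces.

Atrial scaffolds are assembled from mapped spherical-shell patches (the
chambers; patches avoid polar degeneracy) and short cylindrical stubs (the
auricles, pulmonary veins and venae cavae) positioned over the chamber
roofs. Components are built from analytic maps with finite-difference
nodal derivatives (`h = 1e-4` in block coordinates) and merged with
disjoint id spaces; every anatomical structure receives its own
ontology-linked annotation group. The published 282-element heart topology
is deliberately not reproduced; these are reduced, topologically faithful
scaffolds.

The body scaffold (`make_body()`) is a two-layer cylinder whose core is an
annulus (a thin central lumen avoids degenerate elements on the axis).
Axial stations are laid out piecewise-uniformly so that one node ring falls
exactly at the diaphragm fraction; the diaphragm is a landmark node ring,
the spinal cord a dorsal node path, the skin the outer element layer.

`refine_mesh()` splits elements by per-direction factors, sampling new
nodal parameters from the parent interpolation (derivatives rescaled by
1/factor). Children are identified topologically — a new node's key is the
multilinear corner-weight signature of its location — so conforming parents
produce conforming children; if two parents disagree at a shared location
(a C0-only mesh), the disagreement becomes a new derivative version rather
than being averaged away. Mixed orientations of shared faces (one parent's
ξ₁ being another's ξ₂) with unequal factors would produce hanging nodes;
the in-package generators never produce such meshes.

## Fitting

`fit_scaffold()` alternates two steps, four times by default:

1. **Projection.** Every data point is projected to its closest point on
   the current geometry. Candidate elements are seeded on a 3-per-direction
   ξ grid; a short Newton pass (6 iterations) screens plausible elements
   and the near-winners are polished by full Newton — the Gauss-Newton
   matrix augmented with the residual-curvature term, with an active-set
   reduction at the [0,1] bounds, a Gauss-Newton retry when the full model
   is indefinite, and a short golden-section fallback along steepest
   descent (never failing). Iteration stops at a step below 1e-12 or 30
   iterations. Distance ties (< 1e-12 mm) resolve to the lowest element id,
   then the lexicographically smallest ξ. Points whose anatomical term
   matches an annotation group are restricted to that group's elements.
2. **Linear solve.** With projections frozen, the quadratic objective

   Σᵢ wᵢ‖x(ξᵢ; θ) − pᵢ‖² + λ Σₑ∫‖∂(x−X)/∂ξ‖²_F dξ + β Σₑ∫Σⱼₖ‖∂²(x−X)/∂ξⱼ∂ξₖ‖² dξ

   is minimized exactly over all nodal parameters θ, one sparse
   normal-equations system per coordinate component (the matrix is shared).
   X is the reference field: both penalties measure the *deformation*, so
   they vanish at the reference and are invariant under translations of the
   data. Integrals use 3-point Gauss quadrature per direction; mixed
   second-derivative terms are counted twice (symmetric sum). Hard
   fiducial-landmark constraints are imposed exactly through an augmented
   (KKT) system; one step of iterative refinement follows every solve
   because the normal matrix is ill-conditioned when the penalties are
   light. A singular system (too little data with λ = β = 0) raises an
   error advising positive penalties.

The alternation makes the objective non-increasing: re-projection can only
shrink data distances, and each solve is a global minimizer at frozen
correspondences. Defaults are λ = 0.01, β = 0.001, 4 outer iterations,
stopping when the RMS changes by < 1e-6 mm. The strain penalty is a
linearized stand-in for a true tissue strain energy — the
reference-relative first-derivative Frobenius misfit — chosen to keep the
problem linear; the smoothness term is the second-derivative (Sobolev)
seminorm of the displacement. Per-point weights default to 1 and are
configurable per anatomical group.

### What closest-point fitting can and cannot observe

Point-to-surface distance is blind to motion *within* the surface. Two
consequences matter in practice:

* On near-symmetric shapes (a sphere patch under rotation, a cylinder
  under axial slide or rotation about its axis) whole deformation modes
  are invisible to the data term, and the fitted material coordinates are
  then determined by the regularization, not the specimen. Measured on
  synthetic bent atria, blind closest-point fitting recovers the *surface*
  to ~0.03 mm while the *material* error remains of the order of the
  deformation itself.
* Point-to-point correspondences frozen at each outer iteration also make
  large tangential offsets converge very slowly (the objective decreases
  by ~1 %/iteration once the surfaces coincide).

The segmentation workflow this package models resolves this upstream:
fiducial points and concordant structures are registered to material
coordinates on the static scaffold *before* deformable fitting. Two
mechanisms expose that information here: hard landmark constraints in
`fit_config(fixed_landmarks = ...)`, and `fit_scaffold_registered()`, which
consumes contour data that carry their material addresses (as produced by
`sample_contours()`) and fits in a single regularized solve with known
correspondences. Cross-specimen material transfer at the ~1 % level needs
the registered route (or equivalently dense landmarks); pure closest-point
fitting is appropriate when the goal is the specimen's *shape*.

## Embedding, transfer and placement

`embed_points()` in volume mode Newton-solves x(ξ) = p inside candidate
elements (shortlisted by padded bounding boxes, seeded on the 3³ grid,
steps damped to ±0.5 per iteration); a point with no interior solution
falls back to surface projection and is flagged `off_mesh` when its
residual exceeds 1e-6 × the mesh bounding-box diagonal. Surface mode
projects directly. `transfer_points()` evaluates stored material addresses
in any field of a topology-matching mesh; missing elements yield per-point
failure records, never silent drops.

`fiducial_transform()` is the closed-form least-squares similarity
(Umeyama/Kabsch: SVD of the cross-covariance with a determinant correction,
scale from the trace); ≥ 3 non-collinear pairs are required, collinearity
being detected from the source points' second singular value.
`place_organ()` evaluates matched fiducial material points in the organ and
body scaffolds, fits the similarity, and applies it to the organ's nodal
parameters — values affinely, every derivative slot by s·R, which is exact
because an affine map transforms all mixed partials linearly.

## Synthetic specimens

`deform_mesh()` applies analytic deformations whose first, second and
third derivatives are closed-form, so all nodal derivative slots are
updated by the exact chain rule (e.g., the d²/dξ₁dξ₂ slot maps to
J·d₁₂ + H(d₁, d₂)); nothing in the ground truth is numerically
differentiated. Available maps: affine; a circular bend (the z-axis bent to
curvature κ, identity as κ → 0, folding prevented by a Jacobian check at
all quadrature points); a Gaussian radial bulge; rotated/recentered and
composed variants. The bend amplitude convention used in the validation
pipelines is the end deflection as a fraction of the bent axis extent
(κ = 8·fraction/L).

`sample_contours()` emulates segmentation: rings of points at fixed ξ
levels on the outer (and optionally inner — endocardial plus epicardial)
wall surfaces of each annotation group, laid out through the generator's
block grid so a group yields exactly rings × points-per-ring points per
side, plus isotropic Gaussian noise under an explicit seed. Each sampled
point's true material address is recorded, which is what
`fit_scaffold_registered()` consumes. `scatter_cells()` plants cells
uniformly over (element, ξ) in chosen groups and records both the truth
address and the observed position. `registration_error()` reports physical
RMS/worst-case, element-wise ξ RMS, off-mesh counts and unmatched labels.

What the generator does **not** emulate: imaging physics, segmentation
errors other than isotropic point noise, contour topology errors, partial
coverage/occlusion, or anatomically realistic chamber shapes (spheres and
cylinders are deliberately idealized). Passing recovery tests therefore
demonstrates the correctness of the interpolation/fitting/embedding
machinery under known smooth deformations, not segmentation robustness on
real images.

## Numerical choices

* ξ domain closed [0,1]; out-of-range queries beyond 1e-9 are errors,
  smaller excursions are clamped. Quadrature: 3-point Gauss per direction.
* Jacobian positivity is enforced at all quadrature points of 3-D elements
  in `validate_mesh()` and after every synthetic deformation.
* Projection: seeds at ξ ∈ {1/6, 1/2, 5/6} per direction; tie window
  1e-12 mm; Newton step tolerance 1e-12, max 30 iterations; screening
  margin 0.35 × element diameter (a safe bound on the seed-grid
  resolution).
* The native format stores numbers as %.17g with fixed key order: doubles
  round-trip exactly and identical meshes serialize byte-identically; a
  content checksum produces a corruption warning on read.
* Refinement node merging uses a 1e-9 relative parameter tolerance to
  decide whether two parents agree (else a new derivative version is
  created); merge keys round multilinear weights to 12 decimals.
* Test problem sizes: colon fits use the 64-element human preset with a
  few hundred contour points; atria pipelines use the 36-element rat
  preset with ~540 registered points and 40 cells; these sizes keep every
  validation deterministic and quick while exercising all code paths.

## Known limitations

* Fitting optimizes nodal parameters at frozen projections only; ξ and θ
  are never optimized jointly, and the strain penalty is linearized, not a
  hyperelastic energy.
* Closest-point material recovery is fundamentally limited on symmetric
  geometry (see above); use registered data or landmarks for
  cross-specimen material claims.
* Derivative scale factors are not stored separately from derivatives;
  per-element derivative versions cover the same modelling needs at this
  scale (apices, branch points), which diverges from tools that carry
  explicit scale factors.
* `refine_mesh()` assumes shared faces agree in orientation and factors;
  arbitrary externally-built meshes may not.
* The atrial presets are reduced models: component meshes are positioned,
  not topologically fused, which the continuity and fitting machinery
  handles but which does not support transmural conduction-style analyses.
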