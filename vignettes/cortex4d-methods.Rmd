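---
title: "Temporally consistent 4D cortical segmentation: models, parameters and design choices"
author: "Cortex4D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporally consistent 4D cortical segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model,
the parameters that matter, what the phantom does and does not emulate,
the numerical choices, and the limitations we know about. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The segmentation model

A subject's serial scans are segmented jointly. Each time point carries
three nested level sets — signed-distance fields φ₁ ⊆ φ₂ ⊆ φ₃ whose zero
levels are the WM surface, the outer cortical (WM+GM) surface and the
brain (WM+GM+CSF) surface. Tissue memberships are Heaviside differences
of the nested fields (`memberships()`): M_WM = H(φ₁),
M_GM = H(φ₂) − H(φ₁), M_CSF = H(φ₃) − H(φ₂), M_BG = 1 − H(φ₃). We use
the difference form rather than products of Heavisides because, under
the arctangent regularization, only the difference form sums to one
identically at every voxel — which both satisfies the partition-of-unity
requirement exactly and makes the data competition a difference of
adjacent-class energies, the classic coupled-level-set region
competition. Nesting (φ₁ ≤ φ₂ ≤ φ₃ pointwise) is enforced by projection
after every update, so all memberships are nonnegative.

### Local Gaussian intensity model

Brain MR intensities are spatially inhomogeneous, so each class is
described by *local* Gaussian parameters: kernel-weighted mean and
variance fields

u_i = K_σ∗(M_i I) / K_σ∗M_i,  σ_i² = K_σ∗(M_i I²) / K_σ∗M_i − u_i²,

fitted from the current smooth memberships and floored at `varFloor`.
The per-class local fitting energy is the kernel integral of
log σ_i(y) + (I(x) − u_i(y))²/(2σ_i²(y)), evaluated by expanding the
square into four convolutions, and combined with a spatial atlas prior
as d_i = e_i − ω·log(p_i + floor) (MAP composition; ω = 0 recovers the
pure local model).

Two numerical details matter:

- **Soft-membership fitting.** Refitting from hard (sign-based) region
  indicators collapses the WM variance to the post-smoothing noise floor
  wherever WM is locally homogeneous; the resulting hyper-selective WM
  model rejects every partial-volume-shaded voxel and erodes the WM/GM
  boundary by about a voxel. Fitting from the smooth Heaviside
  memberships — which is what the region formulation of the energy
  actually prescribes — keeps transition voxels partially inside the WM
  statistics and removes that bias.
- **Robust truncation.** The arctangent Heaviside has 1/x tails, so a
  voxel deep inside WM still carries ~1% background membership; with
  log-likelihood mismatches of order (105)²/2 this would dominate the
  energy value with terms the flow cannot reduce. The per-voxel class
  minimum is therefore subtracted from the d_i (a φ-independent shift,
  because the memberships sum to one, so every gradient is bit-identical)
  and the remainder truncated at 50 energy units — far above any
  boundary-relevant competition difference, which is of order the
  squared class contrast over the variance (≈ 1–20).

### Thickness constraints

Because the fields are signed distances, the cortical thickness at an
outer-surface point is |φ₁| there; `measureThickness()` extracts
sub-voxel zero crossings of φ₂ and interpolates φ₁ at them. The
volumetric extensions used inside penalty integrals are clamped:
T_outer = max(−φ₁, 0) and T_inner = max(φ₂, 0).

- **Spatial range constraint** (weight λ): one-sided quadratic penalties
  (T − d_max)₊² and (d_min − T)₊², composed with the Heaviside of the
  surface they deflate or inflate, so that the force vanishes whenever
  the thickness lies in [d_min, d_max] = [1, 6.5] mm, deflates the outer
  surface (and inflates the inner) where the cortex is too thick, and
  pushes the surfaces apart where it is too thin. Each penalty is gated
  to a band around its own surface (2 voxels, frozen per outer
  iteration): the outer-measured extension degenerates to zero at the
  inner surface (and vice versa), and without the gate the slow Heaviside
  tails leak a spurious "too thin" force onto the wrong surface.
- **Temporal variation constraint** (weight μ): D_t(x) is the sum of
  thickness differences against the temporal neighbours {t−1, t+1}
  (truncated at the series ends, unnormalized sum), with neighbour
  thickness sampled through the anatomical correspondence. The penalty
  is μ∫D_t H(φ₂): where the current cortex is thicker than its
  neighbours the outer surface is deflated, and conversely. D_t is
  frozen from the state at the start of each outer iteration, which
  keeps it a fixed target during the inner evolution and makes the
  inner-loop energy/gradient pair exactly consistent.

**Which surface receives the temporal force** was a genuinely open
design choice (constraint terms exist for both level sets). We apply it
to the outer surface only: the measured thickness lives on the outer
surface and its deflation/inflation is what changes it, whereas forcing
the inner surface as well squeezes the cortex from both sides and
degrades both WM and GM overlap on phantoms while improving temporal
consistency less. The generic `temporalThicknessForce()` operation still
exposes forces for both surfaces.

## Evolution and numerics

The flows are the *exact gradients of the discretized energy* with the
local Gaussian parameters, the D_t fields and the band masks frozen.
In particular the length term uses forward-difference gradient
magnitudes whose exact adjoint (a backward divergence) appears in the
flow; in the continuum this is the usual −δ_ε(φ)·curvature descent, and
discretely it is what makes the numerical gradient check meaningful (the
suite verifies the flow against central-difference differentiation of
`totalEnergy()` on a 16² two-time-point instance, 95% of band voxels
within 5%). The exported `curvature()` operation reports the divergence
of the outward unit normal (+1/R for a circle, +2/R for a sphere) with
central differences and a 10⁻⁸ gradient floor.

Defaults (config-exposed):

| parameter | default | meaning |
|---|---|---|
| ν | 0.5 | length/smoothness weight |
| λ | 1 | spatial thickness-range weight |
| μ | 0.5 | temporal variation weight (0 = independent 3D) |
| ω | 0.5 | atlas-prior weight |
| [d_min, d_max] | [1, 6.5] mm | admissible thickness range |
| ε | 1.5·min(spacing) | Heaviside/Dirac regularization scale |
| σ (kernel) | 3·min(spacing) | local Gaussian kernel scale |
| Δτ | 0.1·min(spacing)² | time step (satisfies the ν-stability bound) |
| nInner / nOuter | 50 / 3 | inner descent steps per outer alternation |
| varFloor / priorFloor | 1 / 10⁻⁴ | numerical floors |

A CFL-style cap additionally limits each update to 0.45 voxel at
interface-band voxels, and an energy monitor halves Δτ after ten
consecutive increases (aborting below Δτ/64). Reinitialization runs
every iteration by fast marching (second-order upwind, with the front
initialized at sub-voxel accuracy by combining per-axis zero-crossing
distances into a perpendicular distance); the zero level moves by less
than a voxel, sign-derived labels are preserved, and the reconstructed
field has unit gradient away from the interface. Exact idempotence is
limited near the medial axis, where any fast-marching scheme
accumulates O(h) error as characteristics collide — median
reinitialization error on an analytic disk is ≈ 0.04 voxel, with the
largest deviations (≤ 0.5 voxel) confined to the caustic.
`reinitEvery`/`refitEvery` control the reinitialization and model-refit
periods (both default to every iteration).

Hard labels use the nested sign algebra with ties at φ = 0 going to the
inner class. With μ = 0 the 4D pipeline is *bit-identical* to running
each time point separately (the temporal term contributes exact zeros),
which the suite asserts voxel-exactly.

## The phantom

`buildPhantom()` emulates a longitudinal atrophy simulation: a WM core (radius
0.28× the grid extent, optionally perturbed by a sinusoidal boundary
wobble), a GM ribbon of exactly `baselineThickness` (3 mm) built by
signed-distance offsetting (so ground-truth thickness is uniform up to
voxel quantization), a 3 mm CSF shell; five time points with class means
(25, 85, 105) declining by (0, 2, 4) per step; additive Gaussian noise
(σ = 4) followed by 1 mm Gaussian smoothing for the partial-volume
effect; and atrophy inside a sphere on the ribbon: the outermost
in-sphere GM voxels become CSF, linearly in time, so that the final
reduction equals the shrinkage rate (default 0.1) exactly up to voxel
counting. Priors are the blurred (2 mm) baseline truth, standing in for
a population atlas. Everything is deterministic given the seed, and 2D
phantoms are first-class (all operations are dimension-agnostic; 2D
volumes are stored as single-slice 3D NIfTI).

What the phantom does **not** emulate: cortical folding (sulci/gyri and
the associated buried-sulcus thickness ambiguities), bias fields (assumed
removed in preprocessing), rigid misalignment
(series are generated pre-aligned; real series rely on the
correspondence interface), subcortical structures, and scanner-specific
noise spectra. Passing tests on the phantom therefore demonstrate the
mechanics of the energy and its constraints, not clinical-grade
performance on convoluted cortex.

The chosen noise and smoothing levels keep the classes separable, and
the per-time-point baseline (μ = 0) segmentation is consequently very
accurate on the phantom. One observable consequence, documented rather
than hidden: at these accuracy levels the temporal term trades a small
amount of per-time-point boundary overlap (a few thousandths of Dice,
from sub-voxel shifts at knife-edge boundary voxels) for its reduction
in temporal thickness variation. The regime in which temporal coupling
also improves overlap is the one this family of methods was designed
for — baselines with substantial independent per-time-point errors —
which this easy phantom deliberately does not reproduce.

## Problem sizes

The test suite runs 2D phantoms at 128² × 5 time points for the
consistency/accuracy batteries (seeds 1–20, with a 15-inner-iteration,
refit-every-3 budget that sits well inside the convergence plateau),
96²/64² grids for the equivalence and unit suites, and a 16²
two-time-point instance for the gradient check; 3D correctness is
covered at small grids (sphere curvature, 3D round trips). The
acceptance script runs the full default configuration (128², 5 time
points, 50 inner iterations, refit and reinitialize every iteration).

## Known limitations

- Thickness is the signed-distance (closest-point) definition; minimum
  line integral or Laplacian-streamline definitions are out of scope.
- No deformable registration is included: the correspondence interface
  accepts external displacement fields but defaults to identity, which
  is only appropriate for rigidly aligned series.
- The local Gaussian competition places boundaries at a sub-voxel offset
  that depends on the class contrast; on the phantom's declining-contrast
  schedule this induces a small deterministic thickness trend across
  time points on top of the simulated atrophy.
- Narrow-band optimization is not implemented; full-grid updates bound
  practical problem sizes to desk scale (2D ≤ 256², 3D ≤ ~96³).
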