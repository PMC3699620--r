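# Cortex4D

Temporally consistent segmentation of longitudinal (3D + time) brain MR
series with coupled level sets and cortical-thickness constraints.

## The problem

Longitudinal studies of aging and neurodegeneration segment each of a
subject's serial scans into white matter (WM), gray matter (GM) and
cerebrospinal fluid (CSF) and track the cortical thickness over time.
Segmenting every time point independently introduces random,
biologically implausible fluctuations in the measured thickness —
"bumpy" trajectories that mask the slow, smooth cortical thinning of
aging (on the order of hundredths of a millimetre per decade) and reduce
the statistical power of any downstream change analysis. Cortex4D is for
image-analysis researchers who want a self-contained, fully testable
implementation of a 4D (joint space–time) segmentation that suppresses
these artificial variations.

## The model

Each time point *t* carries three nested level-set functions
(signed-distance fields, positive inside):

- φ₁ — the WM surface (inner cortical boundary),
- φ₂ — the WM+GM surface (outer cortical boundary),
- φ₃ — the WM+GM+CSF brain surface,

with region memberships built from regularized Heavisides,
M_WM = H(φ₁), M_GM = H(φ₂) − H(φ₁), M_CSF = H(φ₃) − H(φ₂),
M_BG = 1 − H(φ₃). Because the level sets are signed distances, the
cortical thickness at any point of the outer surface is simply |φ₁|
there. The energy minimized per subject is the sum over time points of

```
E_t = ∫ Σᵢ dᵢ(x) Mᵢ(x) dx                      (local data term)
    + ν Σₖ ∫ δ_ε(φₖ)|∇φₖ| dx                   (length/smoothness)
    + λ ∫ P(thickness) dx                      (spatial range constraint)
    + μ ∫ D_t(x) H(φ₂) dx                      (temporal consistency)
```

where

- dᵢ(x) = eᵢ(x) − ω·log(priorᵢ(x)): a **local Gaussian intensity model**
  (kernel-weighted means/variances per class per location, handling
  intensity inhomogeneity) combined with a spatial atlas prior
  (ω = 0.5);
- P is a one-sided quadratic penalty keeping the thickness inside an
  admissible range [d_min, d_max] = [1, 6.5] mm (λ = 1);
- D_t(x) = Σ_{s∈{t−1,t+1}} [T_t(x) − T_s(w(x))] is the **temporal
  thickness-variation field**: where the current cortex is thicker than
  its temporal neighbours (D_t > 0) the outer surface is deflated, and
  vice versa (μ = 0.5). Neighbour thickness is sampled through a
  pluggable anatomical correspondence (identity for pre-aligned series).

Minimization is by gradient-descent flows of the exact discrete energy,
with nesting projection (φ₂ ← max(φ₂, φ₁), φ₃ ← max(φ₃, φ₂)) and
fast-marching reinitialization of the signed-distance property at every
iteration, alternating with correspondence/thickness-difference
refreshes over 3 outer iterations. Setting μ = 0 reduces the method
exactly to independent per-time-point 3D segmentation.

A built-in **atrophy phantom** generates longitudinal series with known
labels and thickness: WM core + GM ribbon + CSF shell, class means
(25, 85, 105) for (CSF, GM, WM) declining by (0, 2, 4) per time step,
additive Gaussian noise, partial-volume smoothing, and localized GM
atrophy inside a sphere with a prescribed shrinkage rate (r = 0.1 means
10% in-sphere GM volume loss at the last of 5 time points).

## Worked example

```r
library(Cortex4D)

spec <- phantomSpec(rngSeed = 7)       # 128x128, 5 time points, r = 0.1
phantom <- buildPhantom(spec)
result <- run4d(phantom)               # defaults: nu=0.5, lambda=1, mu=0.5
ev <- evaluateResult(result, phantomLabels(phantom))

round(ev$meanThickness, 3)
#> [1] 3.119 3.062 3.026 2.998 2.949
round(ev$temporalVariation, 3)
#> [1] 0.17
round(subset(ev$dice, class == "gm")$dice, 4)
#> [1] 0.9871 0.9823 0.9821 0.9793 0.9645
```

The mean outer-surface thickness declines smoothly across the five time
points (the phantom's true mean declines from 2.89 to 2.86 mm as the
atrophy progresses), and GM overlap with the ground truth stays above
0.96 Dice at every time point. Re-running with
`evolutionParams(mu = 0)` gives the independent 3D baseline: on this
phantom its thickness trajectory has temporal variation 0.236 versus
0.170 for the 4D run — the suppression of artificial thickness
fluctuations that is the method's central claim.

From a shell, the same chain is available as

```sh
inst/cli/cortex4d demo --seed 7 --out demo_out
inst/cli/cortex4d simulate --config cfg.yaml --out sim_out
inst/cli/cortex4d segment --images t1.nii.gz,t2.nii.gz --priors sim_out --out seg_out
inst/cli/cortex4d evaluate --pred seg_out --truth sim_out --out report.json
```

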