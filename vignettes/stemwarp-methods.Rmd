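---
title: "Methods and design of stemwarp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of stemwarp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemwarp)
```

`stemwarp` reconstructs brainstem nuclei and fiber tracts from two
complementary routes — 2D atlas warping of structural slices, and
probabilistic diffusion tractography — and quantifies their agreement and
the age dependence of susceptibility contrast. This vignette is the
package's account of the models it implements, the parameters that
matter, what the synthetic phantoms do and do not emulate, and the design
choices that were genuinely open.

## Coordinate conventions

Voxel indices are 0-based; boxes are half-open; world space is RAS in
millimetres; 4x4 affines act on column vectors and map the index of a
voxel to the world position of its *centre*. Coronal volumes carry the
anteroposterior direction on voxel axis 2, and coronal slice positions
are signed millimetres from the anterior commissure (positive anterior).
`reslice_coronal()` constructs this frame from user-supplied AC and PC
points with trilinear interpolation; its output grid is chosen so the AC
falls exactly on a voxel centre, which makes "distance from AC" labels
exact for acquired slices.

## The landmark warp

The atlas-to-slice registration is a **piecewise-affine interpolating
warp**: the atlas-side landmarks are Delaunay-triangulated (via `deldir`,
with a deterministic 1e-9 jitter keyed to point index to break cocircular
ties) and each triangle carries the unique affine map taking its three
atlas vertices onto their MRI-side partners. This family was chosen
because it is the minimal one that is affine locally and nonlinear
globally, drives the landmark residual to exactly zero (the "minimize the
distance between seed points" objective has nothing left to minimize),
is continuous across shared triangle edges by construction, and possesses
a well-defined per-region Jacobian — the quantity the fold-back control
inspects. Points outside the landmark hull are mapped by the affine of
the nearest triangle; the alternative (clamping to the hull) was rejected
because region contours routinely extend slightly beyond the outermost
landmarks.

**Fold-back control.** A negative per-triangle Jacobian determinant means
the map reverses orientation locally — the warped contours fold over
themselves. `fit_warp_foldback()` then splits the landmark displacement
into `k` equal fractional steps, fits one partial warp between successive
intermediate landmark configurations (re-triangulated each time), and
accepts the smallest `k` in the doubling sequence 2, 4, 8, ... up to
`max_steps` (default 16) for which *every* partial warp is
orientation-preserving. The mechanism that makes this work is the
re-triangulation: as a landmark approaches an edge of the current
triangulation, the Delaunay criterion flips the local diagonal before the
triangle degenerates, so the intermediate steps route the displacement
through a valid triangulation sequence. Displacements that genuinely
reverse the orientation of a landmark triple (for example a landmark
crossing straight through another) cannot be repaired this way at any
`k`; the function then fails loudly, naming the offending triangles —
the correct behaviour, since such a landmark set is inconsistent.

Slice correspondence anchors the first and last atlas plates to acquired
coronal slices and places intermediate plates by linear interpolation
proportional to their atlas spacing, resampling the subject volume
trilinearly at each interpolated position so there is exactly one MRI
slice per plate.

## Lofting, voxelization, overlap

Warped contours are resampled to `n` vertices at uniform arc length,
forced counterclockwise, and rotated so the first vertex has the minimum
polar angle about the contour centroid — a deterministic correspondence
convention adequate for the convex-ish brainstem regions this package
targets (torsion-minimizing matching was considered and rejected as
unneeded). Adjacent rings are joined point-to-point into triangle strips
and the end contours capped with centroid fans; every mesh is audited for
watertightness (each undirected edge shared by exactly two consistently
oriented faces) and oriented to positive enclosed volume. The linear loft
replaces spline (NURBS) surfacing; at the 0.33-0.4 mm grids this package
emulates, the smoothness difference is below voxel scale. Branching
regions (one contour splitting into two) are out of scope.

Voxelization uses the parity rule on rays cast along the third voxel axis
in index space. Ray origins carry a fixed sub-voxel offset (1e-6 /
2.3e-6 voxels) so rays never strike mesh edges exactly, which makes the
result deterministic; voxel centres lying on the surface count as inside.

"Percent overlap" between a tract mask and a warped-atlas mask is
reported as **Jaccard** (`100 * |A & B| / |A | B|`) as the headline
number, with both asymmetric fractions (`|A & B| / |A|` and `/ |B|`)
always included in the record, because the convention behind a bare
"overlap percent" is ambiguous and the three disagree substantially for
masks of unequal size.

## The diffusion model and tracker

The package deliberately replaces Monte-Carlo ball-and-stick posterior
sampling with a lighter model that preserves the *probabilistic*
character of orientation uncertainty:

- **Tensor fit**: per voxel, ordinary least squares on
  `log S = log S0 - b g' D g` over all frames (this is exact at zero
  noise and standard practice otherwise). The principal eigenvector gives
  the fiber axis, fractional anisotropy FA the confidence in it. Voxels
  with non-positive signal are flagged background.
- **Orientation dispersion**: propagation directions are drawn from a
  Watson distribution about the local axis with concentration
  `kappa = kappa0 * FA` (default `kappa0 = 60`), so uncertainty widens
  exactly where anisotropy falls. The sampler draws `u = cos(theta)` on
  `[0, 1]` by rejection from the truncated-exponential envelope
  `exp(kappa * u)` (valid because `u^2 <= u` there), with acceptance at
  least 1/2 for every `kappa` and a log-sum form that is stable at large
  `kappa`; the axial sign is resolved toward the previous direction.
- **Propagation**: fixed-step Euler (default 0.5 mm), bidirectional from
  every seed-voxel centre, 50 samples per seed voxel, stopping on domain
  exit, FA below 0.15, or a turn above 45 degrees per step — orders of
  magnitude matching common probabilistic-tracking defaults. Direction
  look-up interpolates the axis field trilinearly with per-corner sign
  alignment *weighted by corner FA*: near a tract border the principal
  direction of an almost-isotropic neighbour is arbitrary, and unweighted
  interpolation lets that noise deflect streamlines off the tract.
  `kappa` uses the nearest voxel. Sub-voxel seed jitter is off by default
  so that a fixed random seed reproduces results bit-identically.
- **Waypoints**: a streamline is accepted iff it intersects every
  waypoint mask, conjunctively and order-free; whether waypoint order
  mattered in practice is unknowable from a finished analysis, and the
  order-free semantics is the standard one. Visitation maps count each
  accepted streamline once per visited voxel.

Cross-modality transport uses closed-form orthogonal-Procrustes
similarity fits (6 or 7 DOF; for 7 the linear part is one global scale
times a rotation). Intensity-based registration is intentionally not
reimplemented: the phantoms carry known correspondences, and the
transform *contract* — a 4x4 matrix moving masks into diffusion space via
its inverse and visitation maps back via its forward map — is what the
pipeline exercises. Mask resampling is nearest-neighbour so binary masks
stay binary; partial-volume thresholding was rejected to keep masks
crisp.

## Intensity statistics

Region means are computed on raw intensities only; the 0-255 histogram
stretch exists solely as a QC rendering aid (`stretch_intensity()`) and
is never fed into statistics. Ratios divide by the anterior-commissure
mean. Spearman's rho is the Pearson correlation of midranks (ties are
real: the default age preset contains two subjects aged 22), and the
two-sided p-value uses the t approximation
`t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom —
the approximation reproduces published worked examples at this sample
size to 4 decimal places, and an exact permutation alternative
(`spearman_p_exact`, full enumeration for `n <= 8`) is provided but
non-default. Per-region significance uses alpha = 0.05 with no
multiplicity correction, matching per-region reporting conventions; a
Holm option exists but is off by default.

## What the phantoms emulate — and what they do not

- **Structural phantom** (0.4 mm grid, 48 x 64 x 48): background 120;
  nucleus blobs at 130-150; tract tubes at `120 * (1 - h(age))` with
  `h(age) = min(0.02 * age, 0.5)`, a linear-in-age hypointensity law
  chosen because the rank statistics downstream need only monotonicity;
  an age-independent AC analog at 120 so the normalized ratio equals
  `1 - h(age)` exactly at zero noise. Regions are painted in list order
  (later entries win on overlap) and the emitted ground-truth masks are
  post-precedence. Noise is Gaussian — magnitude-image subtleties are
  ignored at this contrast level.
- **DWI phantom** (1 mm grid, 26 x 26 x 24): single prolate tensor with
  eigenvalues (1.7, 0.3, 0.3) x 1e-3 mm^2/s along the local tube tangent,
  isotropic 0.7e-3 outside, signal `S0 exp(-b g' D g)` over 15 b0 frames
  plus 142 directions at b = 1500 s/mm^2 (Fibonacci-lattice directions),
  Rician noise at the requested SNR. Crossing voxels take the
  first-listed tube's tangent — a declared single-fiber limitation; the
  decussation phantom is built so each bundle dominates its own voxels
  outside a small shared core, which is precisely what makes the
  waypoint-at-the-crossing recipe informative. Tube calibers (3 mm) and
  the seed sections drawn at 0.77 of the tube radius reflect, first, how
  a user seeds a tract they can see — comfortably inside its border —
  and, second, the tracker's lateral dispersion: at `kappa ~ 48` a
  half-track wanders about 0.4 mm (rms) over a 20 mm course, so a seed
  flush against the border would leak streamlines out the side of even a
  perfectly straight tract.
- **Atlas-plate fixtures**: region contours are extracted from truth-mask
  slices by marching-squares isocontours, mapped through the *inverse* of
  a known smooth deformation (identity, translation, or a sinusoidal
  field, inverted by fixed-point iteration; the fixture refuses
  non-diffeomorphic specs), with exactly corresponding landmark grids.
  Fold cases are constructed directly from landmark displacements, not
  from deformation fields.
- **Age series**: `ratio = 1.1 + slope * age + N(0, sigma)` with defaults
  slope = -0.02 / year and sigma = 0.05 on the preset ages
  (22, 22, 18, 14, 13, 10, 9, 4).

Passing on these phantoms demonstrates the machinery — exact landmark
interpolation, fold-back, watertight lofting, tensor recovery, waypoint
semantics, rank statistics — under known ground truth. It does not
demonstrate performance on real scans: no susceptibility physics, no EPI
distortion, no partial-volume mixtures, no crossing-fiber modelling, no
anatomical shape realism.

## Problem sizes and tolerances

The test-suite and acceptance phantoms use grids of roughly 50^3
(structural) and 26^3 (diffusion) voxels, 100-157 diffusion frames,
about 2000 streamlines per tracking run, 128-256 vertices per lofted
ring, 16 landmarks per plate, and 200 replicates for the statistical
calibration — sizes at which every ground truth is analytic or
enumerable. Landmark interpolation is asserted to 1e-9 (single-step) and
1e-6 (after fold-back composition); tensor eigen-recovery to 1e-6
relative at zero noise and 1e-8 against a brute-force per-voxel solve;
cylinder volume to 2% (mesh) and 5% (voxelized at 0.4 mm); transforms to
1e-9 round trip. Degenerate inputs (collinear landmarks, duplicate
points, zero-perimeter contours, singular transforms, empty masks,
gradient tables that do not span 3D) raise typed errors rather than
propagating NaNs.

## Known limitations

Single-fiber diffusion model; no intensity-driven registration; no EPI
distortion correction or skull stripping (inputs are assumed
preprocessed NIfTI); single-contour regions only (no branching
topology); Analyze 7.5 is read-only; the fold-back mechanism cannot (and
should not) repair landmark sets whose target configuration is itself
orientation-reversing.
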