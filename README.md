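# stemwarp

Subject-specific visualization of brainstem nuclei and fiber tracts from
high-field MRI. Small deep-brain-stimulation targets such as the
pedunculopontine nucleus (PPN), periaqueductal gray (PAG) and inferior
colliculus (IC) are hard to see on conventional scans; `stemwarp`
implements the combined workflow that makes them tractable at 7T:

1. **Landmark-based atlas warping** — 2D atlas plates (labeled contours
   plus user-placed seed points) are warped onto AC-PC-aligned coronal
   MRI slices with a piecewise-affine map over a Delaunay triangulation
   of the landmarks. The map interpolates every landmark pair exactly and
   is affine in each triangle, so the local Jacobian determinant is
   available everywhere; when it goes negative (fold-over), a *fold-back*
   control splits the displacement into `k` equal partial deformations,
   re-triangulated at each intermediate configuration, until every
   partial step is orientation-preserving.
2. **Surface reconstruction** — warped contours are stacked across slices
   and lofted into watertight triangle meshes, voxelized by a parity
   (ray-crossing) rule, and compared volumetrically.
3. **Probabilistic tractography** — a desk-scale analog of the FSL
   pipeline: per-voxel log-linear diffusion-tensor fits give a principal
   direction and fractional anisotropy FA; streamlines are propagated by
   fixed-step Euler integration of draws from a Watson distribution with
   concentration `kappa = kappa0 * FA`, seeded and filtered by
   seed/waypoint mask semantics (a streamline is accepted iff it
   intersects every waypoint mask), and accumulated into visitation maps.
   7-DOF (rotation + translation + global scale) similarity transforms
   carry masks and maps between structural and diffusion spaces.
4. **Intensity statistics** — region means on the raw 0-255 scale,
   normalized by the anterior-commissure (AC) mean, with Spearman rank
   correlation against age (midranks for ties; two-sided p from
   `t = rho * sqrt((n-2)/(1-rho^2))` with `n-2` df) and ordinary linear
   regression.

Every component is exercisable on generated phantoms: a brainstem-like
structural volume with hypointense tubular tracts (hypointensity
deepening with age) and hyperintense nuclei, a diffusion-weighted series
with a decussating bundle and Rician noise, atlas plates deformed by a
known smooth field, and an 8-subject age series.

## Worked example

```r
library(stemwarp)

# an aging cohort of structural phantoms: SCP/AC intensity ratio vs age
ages <- c(22, 22, 18, 14, 13, 10, 9, 4)
tab <- do.call(rbind, lapply(seq_along(ages), function(i) {
  ph <- make_structural_phantom(structural_phantom_spec(
    age = ages[i], noise_sd = 2, seed = i))
  data.frame(subject = paste0("S", i), age_years = ages[i], region = "SCP",
             ratio = normalize_by_ac(region_mean(ph$volume, ph$masks$SCP),
                                     region_mean(ph$volume, ph$masks$AC)))
}))
age_analysis(tab)
#>   region n    rho df     t       p significant
#> 1    SCP 8 -0.994  6 -22.3 5.3e-07        TRUE
```

The ratio falls from 0.92 at age 4 to 0.56 at age 22 (deeper
susceptibility hypointensity in older subjects), and the rank correlation
with age is strongly negative. Warping a synthetically deformed atlas
plate back onto the subject recovers the ground-truth contours:

```r
ph <- make_structural_phantom(structural_phantom_spec(age = 10))
fx <- make_atlas_plates(ph$masks[c("PPN", "PAG")],
                        deform_spec("sinusoid", amplitude = 1.5, period = 25),
                        n_landmarks = 16, seed = 2)
w  <- fit_warp_foldback(fx$pairs[[1]])
wp <- warp_contours(w, fx$plates[[1]])
#> mean warped-contour error: 0.004 mm (was 0.410 mm before warping)
```

Tracking a straight-tube diffusion phantom from a seed at one end to a
waypoint at the other accepts 96.1% of streamlines (2019 of 2100), and
the thresholded visitation map overlaps the ground-truth tube:

```r
tr <- track(field, seed, list(way), tracking_params(seed = 7))
overlap(threshold_map(tr$visitation, frac = 0.1), truth_tube)
#> <stem_overlap> tract vs truth tube: Jaccard 75.75% (553/730 voxels)
```

The overlap record also carries the asymmetric fractions
(`frac_of_a_pct`, `frac_of_b_pct`) alongside the headline Jaccard
percent, since "percent overlap" is ambiguous between conventions.

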