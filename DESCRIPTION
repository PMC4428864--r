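Package: stemwarp
Title: Brainstem Atlas Warping, Probabilistic Tractography, and
    Intensity Statistics for High-Field MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for subject-specific visualization of brainstem
    nuclei and fiber tracts from high-field MRI. Implements
    landmark-based piecewise-affine warping of 2D atlas plates onto
    coronal MRI slices with fold-back (negative-Jacobian) control,
    lofting of warped contours into watertight triangle meshes with
    parity voxelization and volumetric overlap scoring, simplified
    probabilistic streamline tractography (log-linear tensor fits,
    Watson direction sampling, seed/waypoint mask semantics,
    visitation maps), cross-modality similarity transforms, and
    region-of-interest intensity statistics (anterior-commissure
    normalization, Spearman rank correlation with t-approximation
    p-values, linear regression). Synthetic phantom generators
    provide structural and diffusion-weighted test volumes, deformed
    atlas plates with known ground truth, and age-series tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    oro.nifti,
    deldir,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
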