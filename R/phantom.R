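#' Structural phantom specification
#'
#' Defines the brainstem-like test volume: grid geometry, tubular
#' white-matter tract analogs (hypointense, with age-dependent contrast),
#' hyper/isointense nucleus blobs, and an anterior-commissure analog used
#' as the normalization reference. Intensities emulate susceptibility
#' contrast on the 0-255 scale: background 120; nuclei 130-150; tract
#' tubes at `120 * (1 - h(age))` with `h(age) = min(0.02 * age, 0.5)`, so
#' hypointensity deepens monotonically with age; the AC analog stays at
#' 120 regardless of age. Gaussian noise of sd `noise_sd` is added last.
#'
#' @param age subject age in years.
#' @param dims grid dimensions (default `c(48, 64, 48)`).
#' @param voxel isotropic voxel size in mm (default 0.4, the acquisition
#'   scale this emulates).
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed random seed (fixed seed gives bit-identical volumes).
#' @return A `stem_phantom_spec` list, including the `regions` list
#'   (painted in order; later entries win where regions overlap).
#' @export
structural_phantom_spec <- function(age = 10, dims = c(48L, 64L, 48L),
                                    voxel = 0.4, noise_sd = 0, seed = 1L) {
  ext <- dims * voxel
  cx <- ext[1] / 2; cz <- ext[3] / 2
  h <- min(0.02 * age, 0.5)
  tube_int <- 120 * (1 - h)
  regions <- list(
    list(name = "IC",  kind = "blob", center = c(cx - 3.0, 6.0, cz + 5.0),
         radii = c(1.6, 2.0, 1.6), intensity = 150),
    list(name = "PAG", kind = "blob", center = c(cx, 9.0, cz + 5.6),
         radii = c(1.4, 2.4, 1.4), intensity = 130),
    list(name = "PPN", kind = "blob", center = c(cx + 3.0, 16.0, cz + 3.0),
         radii = c(1.6, 2.4, 1.6), intensity = 140),
    list(name = "ML",  kind = "tube", radius = 1.2, intensity = tube_int,
         path = rbind(c(cx - 3.0, 2.0, cz - 3.0),
                      c(cx - 3.0, ext[2] - 2.6, cz - 3.0))),
    list(name = "LL",  kind = "tube", radius = 1.0, intensity = tube_int,
         path = rbind(c(cx - 5.0, 2.0, cz + 2.0),
                      c(cx - 5.0, ext[2] - 2.6, cz + 2.0))),
    list(name = "SCP", kind = "tube", radius = 1.2, intensity = tube_int,
         path = rbind(c(cx + 4.0, 2.0, cz), c(cx - 4.0, ext[2] - 2.6, cz))),
    list(name = "SCP_contra", kind = "tube", radius = 1.2,
         intensity = tube_int,
         path = rbind(c(cx - 4.0, 2.0, cz), c(cx + 4.0, ext[2] - 2.6, cz))),
    list(name = "AC", kind = "tube", radius = 0.8, intensity = 120,
         path = rbind(c(cx - 3.5, ext[2] - 1.2, cz + 2.4),
                      c(cx + 3.5, ext[2] - 1.2, cz + 2.4)))
  )
  structure(list(age = age, dims = as.integer(dims), voxel = voxel,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 background = 120, hypo = h, regions = regions),
            class = "stem_phantom_spec")
}

# squared distance from points (n x 3) to a polyline (k x 3)
dist2_to_polyline <- function(pts, path) {
  d2 <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(path) - 1L)) {
    a <- path[s, ]; b <- path[s + 1L, ]
    ab <- b - a
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2] +
          (pts[, 3] - a[3]) * ab[3]) / sum(ab^2)
    t <- pmin(1, pmax(0, t))
    dd <- (a[1] + t * ab[1] - pts[, 1])^2 +
          (a[2] + t * ab[2] - pts[, 2])^2 +
          (a[3] + t * ab[3] - pts[, 3])^2
    d2 <- pmin(d2, dd)
  }
  d2
}

#' Generate the structural brainstem phantom
#'
#' Paints the regions of the spec (later entries win on overlap) onto the
#' background, adds Gaussian noise, and emits the volume plus one
#' ground-truth mask per region (post-precedence, so a region's mask is
#' exactly where its intensity was painted).
#'
#' @param spec a [structural_phantom_spec()].
#' @return list: `volume` (`stem_volume`), `masks` (named list of
#'   `stem_mask`), `spec`.
#' @export
make_structural_phantom <- function(spec = structural_phantom_spec()) {
  stopifnot(inherits(spec, "stem_phantom_spec"))
  if (any(vapply(spec$regions, function(r)
        r$kind == "tube" && r$radius <= spec$voxel, logical(1))))
    stop("tube radius must exceed the voxel size")
  d <- spec$dims
  aff <- diag(c(rep(spec$voxel, 3), 1))
  g <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                             k = 0:(d[3] - 1)))
  pts <- g * spec$voxel
  vol <- rep(spec$background, nrow(pts))
  owner <- rep("", nrow(pts))
  for (r in spec$regions) {
    sel <- if (r$kind == "blob") {
      rowSums(sweep(sweep(pts, 2, r$center), 2, r$radii, "/")^2) <= 1
    } else {
      dist2_to_polyline(pts, r$path) <= r$radius^2
    }
    if (!any(sel)) stop("region '", r$name, "' lies outside the grid")
    vol[sel] <- r$intensity
    owner[sel] <- r$name
  }
  set.seed(spec$seed)
  if (spec$noise_sd > 0) vol <- vol + stats::rnorm(length(vol), 0, spec$noise_sd)
  masks <- lapply(stats::setNames(nm = vapply(spec$regions, `[[`, "", "name")),
                  function(nm) as_mask(array(owner == nm, d), aff,
                                       role = "region", label = nm))
  list(volume = as_volume(array(vol, d), aff), masks = masks, spec = spec)
}

#' Default diffusion gradient table
#'
#' Emulates the acquisition geometry this package targets: `n_b0`
#' unweighted frames followed by `n_dir` diffusion-weighted frames at the
#' given b-value, directions spread quasi-uniformly on the sphere by a
#' Fibonacci lattice (deterministic).
#'
#' @param n_dir number of diffusion directions (default 142).
#' @param n_b0 number of b = 0 frames (default 15).
#' @param b b-value in s/mm^2 (default 1500).
#' @return list with `bvals` (length `n_b0 + n_dir`) and `bvecs`
#'   (matching n x 3 unit rows; zero rows for b0 frames).
#' @export
default_gradient_table <- function(n_dir = 142L, n_b0 = 15L, b = 1500) {
  i <- seq_len(n_dir) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n_dir
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  list(bvals = c(rep(0, n_b0), rep(b, n_dir)),
       bvecs = rbind(matrix(0, n_b0, 3), dirs))
}

#' Generate a diffusion-weighted phantom along tube bundles
#'
#' Single-tensor signal model: inside a tube, a prolate tensor with
#' eigenvalues (1.7, 0.3, 0.3) x 10^-3 mm^2/s aligned to the local tube
#' tangent; outside, isotropic diffusivity 0.7 x 10^-3. The signal per
#' frame is `S0 * exp(-b g' D g)`, with Rician noise at the given SNR
#' (sigma = S0 / snr). Where tubes cross, the first-listed tube's tangent
#' wins (declared single-fiber limitation).
#'
#' @param tubes list of tubes: each `list(name, path (k x 3 mm), radius)`.
#' @param bvals,bvecs gradient table (default [default_gradient_table()]).
#' @param dims,voxel DWI grid (default 1 mm voxels, `c(26, 26, 24)`).
#' @param S0 unweighted signal level (default 100).
#' @param snr Rician signal-to-noise ratio; `NULL`, `Inf` or <= 0 gives a
#'   noiseless phantom.
#' @param seed random seed.
#' @return list: `volume` (4D `stem_volume` with gradients attached),
#'   `masks` (named tube masks), `tangents` (nvox x 3 truth directions).
#' @export
make_dwi_phantom <- function(tubes, bvals = NULL, bvecs = NULL,
                             dims = c(26L, 26L, 24L), voxel = 1,
                             S0 = 100, snr = NULL, seed = 1L) {
  if (is.null(bvals)) {
    gt <- default_gradient_table()
    bvals <- gt$bvals; bvecs <- gt$bvecs
  }
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) != 3L) bvecs <- t(bvecs)
  d <- as.integer(dims)
  aff <- diag(c(rep(voxel, 3), 1))
  g <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                             k = 0:(d[3] - 1)))
  pts <- g * voxel
  nvox <- nrow(pts)
  lam_par <- 1.7e-3; lam_perp <- 0.3e-3; iso <- 0.7e-3
  Dvec <- matrix(rep(c(iso, iso, iso, 0, 0, 0), each = nvox), nvox, 6)
  tangents <- matrix(0, nvox, 3)
  owner <- rep("", nvox)
  masks <- list()
  for (tb in tubes) {
    path <- as.matrix(tb$path)
    if (nrow(path) < 2L || sum((path[nrow(path), ] - path[1, ])^2) < 1e-12)
      stop("degenerate tube path: ", tb$name)
    inside <- dist2_to_polyline(pts, path) <= tb$radius^2
    masks[[tb$name]] <- as_mask(array(inside, d), aff, label = tb$name)
    claim <- inside & owner == ""               # first-listed tube wins
    if (any(claim)) {
      owner[claim] <- tb$name
      tg <- tube_tangents(pts[claim, , drop = FALSE], path)
      tangents[claim, ] <- tg
      # prolate tensor aligned to tangent: D = perp*I + (par-perp) t t'
      Dvec[claim, 1] <- lam_perp + (lam_par - lam_perp) * tg[, 1]^2
      Dvec[claim, 2] <- lam_perp + (lam_par - lam_perp) * tg[, 2]^2
      Dvec[claim, 3] <- lam_perp + (lam_par - lam_perp) * tg[, 3]^2
      Dvec[claim, 4] <- (lam_par - lam_perp) * tg[, 1] * tg[, 2]
      Dvec[claim, 5] <- (lam_par - lam_perp) * tg[, 1] * tg[, 3]
      Dvec[claim, 6] <- (lam_par - lam_perp) * tg[, 2] * tg[, 3]
    }
  }
  G <- cbind(bvecs[, 1]^2, bvecs[, 2]^2, bvecs[, 3]^2,
             2 * bvecs[, 1] * bvecs[, 2], 2 * bvecs[, 1] * bvecs[, 3],
             2 * bvecs[, 2] * bvecs[, 3])
  Q <- Dvec %*% t(G)                       # nvox x nframes: g' D g
  S <- S0 * exp(-sweep(Q, 2, bvals, "*"))
  set.seed(seed)
  if (!is.null(snr) && is.finite(snr) && snr > 0) {
    sg <- S0 / snr
    n1 <- matrix(stats::rnorm(length(S), 0, sg), nrow(S))
    n2 <- matrix(stats::rnorm(length(S), 0, sg), nrow(S))
    S <- sqrt((S + n1)^2 + n2^2)
  }
  vol <- as_volume(array(S, c(d, length(bvals))), aff,
                   bvals = bvals, bvecs = bvecs)
  list(volume = vol, masks = masks, tangents = tangents)
}

# unit tangent of the nearest polyline segment for each point
tube_tangents <- function(pts, path) {
  nseg <- nrow(path) - 1L
  best <- rep(Inf, nrow(pts))
  seg_id <- rep(1L, nrow(pts))
  for (s in seq_len(nseg)) {
    a <- path[s, ]; b <- path[s + 1L, ]
    ab <- b - a
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2] +
          (pts[, 3] - a[3]) * ab[3]) / sum(ab^2)
    t <- pmin(1, pmax(0, t))
    dd <- (a[1] + t * ab[1] - pts[, 1])^2 +
          (a[2] + t * ab[2] - pts[, 2])^2 +
          (a[3] + t * ab[3] - pts[, 3])^2
    upd <- dd < best
    best[upd] <- dd[upd]
    seg_id[upd] <- s
  }
  tg <- path[seg_id + 1L, , drop = FALSE] - path[seg_id, , drop = FALSE]
  tg / sqrt(rowSums(tg^2))
}

#' Deformation field specifications for atlas-plate fixtures
#'
#' Smooth invertible in-plane deformations `f` mapping atlas coordinates
#' to subject coordinates: `identity`, a pure `translation` by `shift`
#' (mm), or a `sinusoid` displacement
#' `f(p) = p + amplitude * sin(2 pi p' / period)` (coordinates swapped so
#' each axis displaces with the other), diffeomorphic for
#' `2 pi amplitude / period < 1`.
#'
#' @param type one of `"identity"`, `"translation"`, `"sinusoid"`.
#' @param shift length-2 translation (mm).
#' @param amplitude sinusoid displacement amplitude (mm).
#' @param period sinusoid period (mm).
#' @return A `stem_deform` with `fwd(p)` (n x 2 -> n x 2) and fields.
#' @export
deform_spec <- function(type = c("identity", "translation", "sinusoid"),
                        shift = c(2, 1), amplitude = 1.5, period = 25) {
  type <- match.arg(type)
  fwd <- switch(type,
    identity = function(p) p,
    translation = function(p) sweep(p, 2, shift, "+"),
    sinusoid = function(p) p + amplitude *
      cbind(sin(2 * pi * p[, 2] / period), sin(2 * pi * p[, 1] / period)))
  structure(list(type = type, shift = shift, amplitude = amplitude,
                 period = period, fwd = fwd), class = "stem_deform")
}

# numerically invert a stem_deform at subject points (fixed-point; the
# displacement is a contraction for diffeomorphic specs)
deform_inverse <- function(deform, pts) {
  a <- pts
  for (it in 1:100) {
    disp <- deform$fwd(a) - a
    a_new <- pts - disp
    if (max(abs(a_new - a)) < 1e-12) return(a_new)
    a <- a_new
  }
  a
}

# max |displacement gradient| check: the fixture must be diffeomorphic
deform_check <- function(deform, bbox) {
  gx <- seq(bbox[1, 1], bbox[2, 1], length.out = 15)
  gy <- seq(bbox[1, 2], bbox[2, 2], length.out = 15)
  p <- as.matrix(expand.grid(gx, gy))
  h <- 1e-4
  fx <- (deform$fwd(sweep(p, 2, c(h, 0), "+")) -
         deform$fwd(sweep(p, 2, c(h, 0), "-"))) / (2 * h)
  fy <- (deform$fwd(sweep(p, 2, c(0, h), "+")) -
         deform$fwd(sweep(p, 2, c(0, h), "-"))) / (2 * h)
  dets <- fx[, 1] * fy[, 2] - fx[, 2] * fy[, 1]
  if (any(dets <= 0))
    stop("spec error: deformation folds the domain (non-positive Jacobian)")
  invisible(TRUE)
}

#' Build atlas plates from truth masks through a known deformation
#'
#' Extracts each region's contour on the chosen coronal slices of the
#' ground-truth masks (marching-squares isocontour at 0.5), maps the
#' contours and a jittered grid of landmark points through the inverse of
#' the deformation to create "atlas" plates, and returns exact landmark
#' correspondences plus the subject-side truth contours for recovery
#' scoring. Fold cases are not built here (the fixture must be
#' diffeomorphic); they are constructed directly from landmark
#' displacements.
#'
#' @param masks named list of `stem_mask` on a coronal grid (slice axis 2).
#' @param deform a [deform_spec()] (atlas -> subject).
#' @param slices 0-based slice indices; default: every 4th slice where the
#'   first mask is present.
#' @param n_landmarks landmarks per plate (default 16).
#' @param seed jitter seed.
#' @return list: `plates` (atlas side), `pairs` (list of
#'   `stem_landmarks`, atlas -> subject), `truth` (subject-side plates),
#'   `deform`.
#' @export
make_atlas_plates <- function(masks, deform = deform_spec("identity"),
                              slices = NULL, n_landmarks = 16L, seed = 1L) {
  stopifnot(length(masks) >= 1L)
  aff <- masks[[1]]$affine
  d <- dim(masks[[1]]$data)
  if (is.null(slices)) {
    present <- which(apply(masks[[1]]$data, 2, any)) - 1L
    slices <- present[seq(1L, length(present), by = 4L)]
    if (length(slices) < 2L) slices <- range(present)
  }
  # in-plane mm coordinates of pixel centres (axes 1 and 3)
  ux <- (0:(d[1] - 1)) * aff[1, 1] + aff[1, 4]
  uz <- (0:(d[3] - 1)) * aff[3, 3] + aff[3, 4]
  set.seed(seed)
  plates <- list(); pairs <- list(); truth <- list()
  for (si in seq_along(slices)) {
    j <- slices[si]
    pos <- aff[2, 2] * j + aff[2, 4]
    contours <- list()
    for (nm in names(masks)) {
      sl <- masks[[nm]]$data[, j + 1L, ]
      if (sum(sl) < 4L) next
      cl <- grDevices::contourLines(ux, uz, sl + 0, levels = 0.5)
      if (!length(cl)) next
      areas <- vapply(cl, function(cc)
        abs(polygon_area(cbind(cc$x, cc$y))), numeric(1))
      cc <- cl[[which.max(areas)]]
      contours[[nm]] <- cbind(cc$x, cc$y)
    }
    if (!length(contours)) next
    allv <- do.call(rbind, contours)
    bb <- rbind(apply(allv, 2, min) - 2, apply(allv, 2, max) + 2)
    deform_check(deform, bb)
    nside <- ceiling(sqrt(n_landmarks))
    gx <- seq(bb[1, 1], bb[2, 1], length.out = nside)
    gy <- seq(bb[1, 2], bb[2, 2], length.out = nside)
    lm_subj <- as.matrix(expand.grid(gx, gy))[seq_len(n_landmarks), ,
                                              drop = FALSE]
    jit <- matrix(stats::runif(2 * n_landmarks, -0.2, 0.2), ncol = 2) *
      c(diff(gx[1:2]) %||% 1, diff(gy[1:2]) %||% 1)
    lm_subj <- lm_subj + jit
    lm_atlas <- deform_inverse(deform, lm_subj)
    atlas_contours <- lapply(contours, function(cc) deform_inverse(deform, cc))
    id <- sprintf("plate_%02d", si)
    plates[[id]] <- atlas_plate(id, pos, atlas_contours, lm_atlas)
    truth[[id]] <- atlas_plate(id, pos, contours, lm_subj)
    pairs[[id]] <- landmark_pairs(lm_atlas, lm_subj)
  }
  if (length(plates) < 2L) stop("fewer than 2 usable plates extracted")
  list(plates = unname(plates), pairs = unname(pairs),
       truth = unname(truth), deform = deform)
}

#' Generate a synthetic age-versus-intensity-ratio series
#'
#' Emulates an 8-subject aging series: the normalized intensity ratio
#' declines linearly with age plus Gaussian noise,
#' `ratio = 1.1 + slope * age + N(0, sigma)`. Ages come from the preset
#' `c(22, 22, 18, 14, 13, 10, 9, 4)` when `n = 8` (note the tied ages),
#' otherwise uniformly from the 4-22 year range.
#'
#' @param n number of subjects (>= 3).
#' @param slope ratio change per year (default -0.02).
#' @param sigma noise sd on the ratio (default 0.05).
#' @param seed random seed.
#' @param ages optional explicit ages; `"preset"` forces the 8-age preset.
#' @param region region label for the table (default "SCP").
#' @return data.frame: `subject`, `age_years`, `region`, `mean_intensity`,
#'   `ratio`.
#' @export
make_age_series <- function(n = 8L, slope = -0.02, sigma = 0.05, seed = 1L,
                            ages = NULL, region = "SCP") {
  if (n < 3L) stop("need n >= 3 subjects")
  preset <- c(22, 22, 18, 14, 13, 10, 9, 4)
  set.seed(seed)
  if (is.null(ages)) {
    ages <- if (n == 8L) preset else stats::runif(n, 4, 22)
  } else if (identical(ages, "preset")) {
    if (n != 8L) stop("preset ages require n = 8")
    ages <- preset
  }
  if (length(ages) != n) stop("ages length must equal n")
  ratio <- 1.1 + slope * ages + stats::rnorm(n, 0, sigma)
  data.frame(subject = sprintf("S%d", seq_len(n)), age_years = ages,
             region = region, mean_intensity = ratio * 120, ratio = ratio)
}

#' Default DWI tube bundles
#'
#' Two crossing bundles (the decussation analog) plus two parallel
#' ascending bundles, expressed in the DWI grid's world coordinates. Tube
#' calibers (3 mm; 2.6 mm for the thinner bundle) reflect brainstem tract
#' sizes at the emulated 1 mm diffusion resolution.
#'
#' @param dims,voxel DWI grid geometry.
#' @return list of tube definitions for [make_dwi_phantom()].
#' @export
default_dwi_tubes <- function(dims = c(26L, 26L, 24L), voxel = 1) {
  ext <- dims * voxel
  cx <- ext[1] / 2; cz <- ext[3] / 2
  list(
    list(name = "SCP", radius = 3,
         path = rbind(c(cx + 5, 2, cz - 4), c(cx - 5, ext[2] - 3, cz - 4))),
    list(name = "SCP_contra", radius = 3,
         path = rbind(c(cx - 5, 2, cz - 4), c(cx + 5, ext[2] - 3, cz - 4))),
    list(name = "ML", radius = 3,
         path = rbind(c(cx - 6, 2, cz + 4), c(cx - 6, ext[2] - 3, cz + 4))),
    list(name = "LL", radius = 2.6,
         path = rbind(c(cx + 5, 2, cz + 4), c(cx + 5, ext[2] - 3, cz + 4)))
  )
}

#' Cross-section seed/waypoint mask along a tube
#'
#' Builds the mask a user would draw on a few coronal slices of a visible
#' tract: voxels whose in-plane distance to the tube path is at most
#' `shrink * radius` (drawn comfortably inside the tract border) on the
#' given slices.
#'
#' @param tube a tube definition (`name`, `path`, `radius`).
#' @param dims,voxel grid geometry (must match the DWI phantom's).
#' @param j_slices 0-based slice indices along axis 2.
#' @param shrink fraction of the tube radius to keep (default 0.77).
#' @param role mask role tag.
#' @return A `stem_mask`.
#' @export
tube_section_mask <- function(tube, dims = c(26L, 26L, 24L), voxel = 1,
                              j_slices, shrink = 0.77, role = "seed") {
  d <- as.integer(dims)
  g <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                             k = 0:(d[3] - 1)))
  pts <- g * voxel
  sel <- dist2_to_polyline(pts, as.matrix(tube$path)) <=
    (shrink * tube$radius)^2 & (g[, 2] %in% j_slices)
  as_mask(array(sel, d), diag(c(rep(voxel, 3), 1)), role = role,
          label = tube$name)
}
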