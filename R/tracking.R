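#' Tracking parameters
#'
#' Controls for the probabilistic streamline propagator: fixed Euler step
#' size, per-step curvature limit, anisotropy stopping threshold, number of
#' samples per seed voxel and the random seed (identical seeds give
#' bit-identical results).
#'
#' @param step step size in mm (> 0).
#' @param max_steps maximum Euler steps per half-track.
#' @param curvature maximum turning angle per step, degrees (0 < a <= 90).
#' @param fa_threshold anisotropy below which propagation stops.
#' @param samples streamlines launched per seed voxel (>= 1).
#' @param seed random seed.
#' @return A `stem_params` list.
#' @export
tracking_params <- function(step = 0.5, max_steps = 200L, curvature = 45,
                            fa_threshold = 0.15, samples = 50L, seed = 1L) {
  if (step <= 0) stop("step must be positive")
  if (curvature <= 0 || curvature > 90)
    stop("curvature threshold must be in (0, 90] degrees")
  if (samples < 1L) stop("samples must be >= 1")
  structure(list(step = step, max_steps = as.integer(max_steps),
                 curvature = curvature, fa_threshold = fa_threshold,
                 samples = as.integer(samples), seed = as.integer(seed)),
            class = "stem_params")
}

# Draw u = cos(angle to axis) in [0, 1] from the Watson bipolar density
# f(u) proportional to exp(kappa u^2), per element of kappa. Rejection from
# the truncated-exponential envelope exp(kappa u) (valid since u^2 <= u on
# [0, 1]); acceptance >= 1/2 for every kappa. Numerically stable at large
# kappa via u = 1 + log(U + (1-U) e^-kappa)/kappa.
rwatson_cos <- function(kappa) {
  n <- length(kappa)
  u <- numeric(n)
  todo <- seq_len(n)
  small <- kappa < 1e-8
  u[small] <- stats::runif(sum(small))
  todo <- todo[!small]
  while (length(todo)) {
    k <- kappa[todo]
    U1 <- stats::runif(length(todo))
    U2 <- stats::runif(length(todo))
    cand <- 1 + log(U1 + (1 - U1) * exp(-k)) / k
    ok <- U2 <= exp(k * (cand^2 - cand))
    u[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  u
}

# Vectorized Watson draws about per-row axes mu (n x 3, unit) with
# per-element kappa. Sign of the result matches prev (n x 3) when given,
# otherwise it is random (the axis is symmetric).
sample_watson <- function(mu, kappa, prev = NULL) {
  n <- nrow(mu)
  live <- rowSums(mu^2) > 0.5          # zero axis = background, no draw
  if (!all(live)) {
    out <- matrix(0, n, 3)
    if (any(live))
      out[live, ] <- sample_watson(mu[live, , drop = FALSE], kappa[live],
                                   prev = if (is.null(prev)) NULL
                                          else prev[live, , drop = FALSE])
    return(out)
  }
  u <- rwatson_cos(kappa)
  phi <- stats::runif(n, 0, 2 * pi)
  # orthonormal frame per axis: pick the cardinal least aligned with mu
  pick <- max.col(-abs(mu), ties.method = "first")
  a <- matrix(0, n, 3)
  a[cbind(seq_len(n), pick)] <- 1
  e1 <- cbind(mu[, 2] * a[, 3] - mu[, 3] * a[, 2],
              mu[, 3] * a[, 1] - mu[, 1] * a[, 3],
              mu[, 1] * a[, 2] - mu[, 2] * a[, 1])
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(mu[, 2] * e1[, 3] - mu[, 3] * e1[, 2],
              mu[, 3] * e1[, 1] - mu[, 1] * e1[, 3],
              mu[, 1] * e1[, 2] - mu[, 2] * e1[, 1])
  st <- sqrt(pmax(0, 1 - u^2))
  v <- mu * u + e1 * (st * cos(phi)) + e2 * (st * sin(phi))
  sgn <- if (is.null(prev)) sign(stats::runif(n) - 0.5)
         else sign(rowSums(v * prev))
  sgn[sgn == 0] <- 1
  v * sgn
}

# Trilinear interpolation of the direction field at fractional 0-based
# voxel coords, with per-corner sign alignment to ref (n x 3) so the axial
# ambiguity does not cancel the average, and corner weights multiplied by
# corner anisotropy so near-isotropic voxels (whose principal direction is
# arbitrary) do not corrupt the mean near tract borders. Returns unit
# rows; zero rows where interpolation degenerates (caller stops).
interp_directions <- function(field, ijk, ref) {
  d <- dim(field$fa)
  n <- nrow(ijk)
  hi <- matrix(rep(d - 1, each = n), ncol = 3)
  i0 <- pmax(matrix(0, n, 3), pmin(floor(ijk), hi))
  f <- pmin(matrix(1, n, 3), pmax(matrix(0, n, 3), ijk - i0))
  acc <- matrix(0, n, 3)
  dm <- matrix(field$dir, prod(d), 3)
  for (corner in 0:7) {
    off <- c(corner %% 2, (corner %/% 2) %% 2, corner %/% 4)
    ii <- pmin(i0 + matrix(off, n, 3, byrow = TRUE),
               matrix(rep(d - 1, each = n), ncol = 3))
    w <- apply(cbind(ifelse(off[1] == 1, f[, 1], 1 - f[, 1]),
                     ifelse(off[2] == 1, f[, 2], 1 - f[, 2]),
                     ifelse(off[3] == 1, f[, 3], 1 - f[, 3])), 1, prod)
    lin <- ii[, 1] + d[1] * (ii[, 2] + d[2] * ii[, 3]) + 1L
    dv <- dm[lin, , drop = FALSE]
    flip <- sign(rowSums(dv * ref))
    flip[flip == 0] <- 1
    acc <- acc + dv * (w * field$fa[lin] * flip)
  }
  nrm <- sqrt(rowSums(acc^2))
  ok <- nrm > 1e-12
  acc[ok, ] <- acc[ok, , drop = FALSE] / nrm[ok]
  acc[!ok, ] <- 0
  acc
}

# nearest-voxel kappa / fa lookups at fractional 0-based coords
nearest_lookup <- function(arr, ijk) {
  d <- dim(arr)
  ii <- round(ijk)
  ok <- ii[, 1] >= 0 & ii[, 1] < d[1] & ii[, 2] >= 0 & ii[, 2] < d[2] &
        ii[, 3] >= 0 & ii[, 3] < d[3]
  out <- rep(NA_real_, nrow(ijk))
  out[ok] <- arr[ii[ok, , drop = FALSE] + 1L]
  out
}

#' Sample a propagation direction from the orientation field
#'
#' Draws from a Watson distribution about the trilinearly interpolated
#' principal direction at `p`, with the nearest voxel's concentration
#' `kappa`. The sign of the draw is chosen so its dot product with `prev`
#' is non-negative (the fiber axis itself is sign-ambiguous).
#'
#' @param field a `stem_field`.
#' @param p world point (length 3 or n x 3).
#' @param prev previous unit direction(s), or `NULL` for a random sign.
#' @return n x 3 matrix of unit vectors.
#' @export
sample_direction <- function(field, p, prev = NULL) {
  p <- rbind3(p)
  ijk <- t(solve(field$affine) %*% rbind(t(p), 1))[, 1:3, drop = FALSE]
  ref <- if (is.null(prev)) {
    mu0 <- matrix(0, nrow(p), 3)
    lin <- round(ijk)
    dmat <- matrix(field$dir, length(field$fa), 3)
    d <- dim(field$fa)
    okv <- lin[, 1] >= 0 & lin[, 1] < d[1] & lin[, 2] >= 0 &
           lin[, 2] < d[2] & lin[, 3] >= 0 & lin[, 3] < d[3]
    mu0[okv, ] <- dmat[lin[okv, 1] + d[1] * (lin[okv, 2] + d[2] * lin[okv, 3]) + 1L, ,
                       drop = FALSE]
    mu0
  } else rbind3(prev)
  mu <- interp_directions(field, ijk, ref)
  kap <- nearest_lookup(field$kappa, ijk)
  kap[is.na(kap)] <- 0
  sample_watson(mu, kap, prev = if (is.null(prev)) NULL else rbind3(prev))
}

#' Probabilistic streamline tracking with seed and waypoint masks
#'
#' From the centre of every seed voxel, `params$samples` streamlines are
#' propagated bidirectionally by fixed-step Euler integration of Watson
#' draws from the orientation field. A half-track stops when it leaves the
#' field, enters a voxel with anisotropy below the threshold, or the
#' sampled direction turns by more than the curvature limit in one step. A
#' streamline is accepted iff it intersects every waypoint mask
#' (conjunctive, order-free). The visitation map counts accepted
#' streamlines once per visited voxel.
#'
#' @param field a `stem_field`.
#' @param seeds nonempty `stem_mask` on the field grid.
#' @param waypoints list of `stem_mask` on the field grid (may be empty).
#' @param params a [tracking_params()] object.
#' @return list with `streamlines` (a `stem_streamset`: `paths`,
#'   `accepted`, `reason`) and `visitation` (a `stem_vmap`: `counts` array,
#'   `total_samples`, `affine`).
#' @export
track <- function(field, seeds, waypoints = list(), params = tracking_params()) {
  if (!any(seeds$data)) stop("seed mask is empty")
  if (!all(dim(seeds$data) == dim(field$fa)))
    stop("seed mask must live on the field grid")
  for (w in waypoints)
    if (!all(dim(w$data) == dim(field$fa)))
      stop("waypoint masks must live on the field grid")
  set.seed(params$seed)
  d <- dim(field$fa)
  seed_ijk <- which(seeds$data, arr.ind = TRUE) - 1L
  ns <- nrow(seed_ijk) * params$samples
  start_ijk <- seed_ijk[rep(seq_len(nrow(seed_ijk)), each = params$samples), ,
                        drop = FALSE]
  start_w <- t(field$affine %*% rbind(t(start_ijk), 1))[, 1:3, drop = FALSE]
  d0 <- sample_direction(field, start_w, prev = NULL)
  cos_thr <- cos(params$curvature * pi / 180)

  propagate <- function(pos, dir) {
    n <- nrow(pos)
    hist <- array(NA_real_, c(params$max_steps + 1L, n, 3))
    hist[1, , ] <- pos
    active <- rowSums(dir^2) > 0.5
    reason <- rep(NA_character_, n)
    reason[!active] <- "low anisotropy"
    step_of <- rep(1L, n)
    for (s in seq_len(params$max_steps)) {
      if (!any(active)) break
      idx <- which(active)
      newp <- pos[idx, , drop = FALSE] + params$step * dir[idx, , drop = FALSE]
      ijk <- t(solve(field$affine) %*% rbind(t(newp), 1))[, 1:3, drop = FALSE]
      fa <- nearest_lookup(field$fa, ijk)
      out <- is.na(fa)
      low <- !out & fa < params$fa_threshold
      stop_now <- out | low
      reason[idx[out]] <- "left volume"
      reason[idx[low]] <- "low anisotropy"
      keep <- idx[!stop_now]
      active[idx[stop_now]] <- FALSE
      if (length(keep)) {
        kp <- newp[!stop_now, , drop = FALSE]
        pos[keep, ] <- kp
        step_of[keep] <- s + 1L
        hist[s + 1L, keep, ] <- kp
        nd <- sample_direction(field, kp, prev = dir[keep, , drop = FALSE])
        turn <- rowSums(nd * dir[keep, , drop = FALSE])
        sharp <- turn < cos_thr
        reason[keep[sharp]] <- "curvature stop"
        active[keep[sharp]] <- FALSE
        dir[keep[!sharp], ] <- nd[!sharp, , drop = FALSE]
      }
    }
    reason[is.na(reason)] <- "max steps"
    list(hist = hist, nstep = step_of, reason = reason)
  }

  fwd <- propagate(start_w, d0)
  bwd <- propagate(start_w, -d0)

  # assemble per-streamline polylines (backward reversed + seed + forward)
  paths <- vector("list", ns)
  for (i in seq_len(ns)) {
    b <- bwd$hist[seq_len(bwd$nstep[i]), i, , drop = FALSE]
    f <- fwd$hist[seq_len(fwd$nstep[i]), i, , drop = FALSE]
    bmat <- matrix(b, ncol = 3)
    fmat <- matrix(f, ncol = 3)
    paths[[i]] <- rbind(bmat[rev(seq_len(nrow(bmat))[-1]), , drop = FALSE],
                        fmat)
  }

  # waypoint audit: vertex voxel membership, conjunctive over all masks
  nv <- vapply(paths, nrow, integer(1))
  sid <- rep(seq_len(ns), nv)
  allp <- do.call(rbind, paths)
  vik <- round(t(solve(field$affine) %*% rbind(t(allp), 1))[, 1:3, drop = FALSE])
  inb <- vik[, 1] >= 0 & vik[, 1] < d[1] & vik[, 2] >= 0 & vik[, 2] < d[2] &
         vik[, 3] >= 0 & vik[, 3] < d[3]
  accepted <- rep(TRUE, ns)
  for (w in waypoints) {
    hit <- logical(ns)
    m <- logical(nrow(allp))
    m[inb] <- w$data[vik[inb, , drop = FALSE] + 1L]
    hit[unique(sid[m])] <- TRUE
    accepted <- accepted & hit
  }
  reason <- ifelse(accepted, "accepted", "missed waypoint")

  counts <- array(0L, d)
  if (any(accepted)) {
    ok <- inb & accepted[sid]
    lin <- vik[ok, 1] + d[1] * (vik[ok, 2] + d[2] * vik[ok, 3]) + 1L
    key <- !duplicated(cbind(sid[ok], lin))        # once per voxel per line
    tab <- table(lin[key])
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  streams <- structure(list(paths = paths, accepted = accepted,
                            reason = reason,
                            stop_reason_fwd = fwd$reason,
                            stop_reason_bwd = bwd$reason),
                       class = "stem_streamset")
  vmap <- structure(list(counts = counts, total_samples = ns,
                         affine = field$affine), class = "stem_vmap")
  list(streamlines = streams, visitation = vmap)
}

#' @export
print.stem_streamset <- function(x, ...) {
  cat("<stem_streamset> ", length(x$paths), " streamlines, ",
      sum(x$accepted), " accepted\n", sep = "")
  invisible(x)
}

#' @export
print.stem_vmap <- function(x, ...) {
  cat("<stem_vmap> ", sum(x$counts > 0), " visited voxels, max count ",
      max(x$counts), " of ", x$total_samples, " samples\n", sep = "")
  invisible(x)
}

#' Threshold a visitation map into a binary tract mask
#'
#' @param vm a `stem_vmap`.
#' @param frac threshold as a fraction of the maximum count, or
#' @param absolute an absolute count threshold (used if given).
#' @return A `stem_mask`; the threshold used is stored in attribute
#'   `threshold`. Empty results raise a warning.
#' @export
threshold_map <- function(vm, frac = 0.1, absolute = NULL) {
  if (all(vm$counts == 0)) {
    warning("visitation map is empty", call. = FALSE)
    thr <- absolute %||% 0
  } else {
    thr <- absolute %||% (frac * max(vm$counts))
  }
  sel <- vm$counts >= thr & vm$counts > 0
  if (!any(sel)) warning("thresholded tract mask is empty", call. = FALSE)
  out <- structure(list(data = array(sel, dim(vm$counts)),
                        affine = vm$affine, role = "region", label = "tract"),
                   class = "stem_mask")
  attr(out, "threshold") <- thr
  out
}

#' Export streamlines as TrackVis .trk
#'
#' Minimal TrackVis writer (voxel-size header fields from the field grid;
#' no scalars or properties).
#'
#' @param s a `stem_streamset`.
#' @param path output `.trk` path.
#' @param voxel_size length-3 voxel size in mm.
#' @param dim length-3 grid dims.
#' @export
write_trk <- function(s, path, voxel_size = c(1, 1, 1), dim = c(1, 1, 1)) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), raw(1)), con)
  writeBin(as.integer(dim), con, size = 2)
  writeBin(as.numeric(voxel_size), con, size = 4)
  writeBin(numeric(3), con, size = 4)                 # origin
  writeBin(integer(1), con, size = 2)                 # n_scalars
  writeBin(raw(200), con)                             # scalar names
  writeBin(integer(1), con, size = 2)                 # n_properties
  writeBin(raw(200), con)                             # property names
  writeBin(as.numeric(diag(4)), con, size = 4)        # vox_to_ras
  writeBin(raw(444), con)                             # reserved
  writeBin(c(charToRaw("RAS"), raw(1)), con)          # voxel_order
  writeBin(c(charToRaw("RAS"), raw(1)), con)          # pad2
  writeBin(numeric(6), con, size = 4)                 # image orientation
  writeBin(raw(8), con)                               # pad1 + invert flags
  writeBin(as.integer(length(s$paths)), con, size = 4)
  writeBin(2L, con, size = 4)                         # version
  writeBin(1000L, con, size = 4)                      # hdr_size
  for (p in s$paths) {
    writeBin(nrow(p), con, size = 4)
    writeBin(as.numeric(t(p)), con, size = 4)
  }
  invisible(path)
}

# nearest-neighbour resampling of a numeric grid (visitation counts) onto a
# target grid through a world transform t: source world -> target world
resample_counts <- function(counts, src_affine, t, target) {
  d <- dim(target$data)[1:3]
  g <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                             k = 0:(d[3] - 1)))
  world_t <- base::t(target$affine %*% rbind(base::t(g), 1))[, 1:3]
  world_s <- apply_transform(invert_transform(t), world_t)
  ijk <- round(base::t(solve(src_affine) %*% rbind(base::t(world_s), 1))[, 1:3])
  ds <- dim(counts)
  ok <- ijk[, 1] >= 0 & ijk[, 1] < ds[1] & ijk[, 2] >= 0 & ijk[, 2] < ds[2] &
        ijk[, 3] >= 0 & ijk[, 3] < ds[3]
  val <- numeric(nrow(g))
  val[ok] <- counts[ijk[ok, , drop = FALSE] + 1L]
  array(val, d)
}

#' Run a named tract recipe against a warped-atlas mask
#'
#' The full cross-modality loop: the structural-space seed and waypoint
#' masks are transported into DWI space through the inverse of the
#' DWI-to-structural transform, tracking is run there, the visitation map
#' is transported back onto the structural grid, thresholded, and compared
#' with the supplied atlas-derived mask.
#'
#' @param recipe list with `seed` (structural-grid `stem_mask`),
#'   `waypoints` (list of structural-grid masks), `atlas_mask`
#'   (structural-grid mask to compare against), `xfm` (`stem_xfm` mapping
#'   DWI world coordinates to structural world coordinates) and optionally
#'   `threshold_frac` (default 0.1).
#' @param field a `stem_field` on the DWI grid.
#' @param params a [tracking_params()].
#' @param structural_grid a `stem_volume`/`stem_mask` defining the
#'   structural grid (defaults to the atlas mask's grid).
#' @return list: `tract_mask` (structural grid), `overlap`
#'   (`stem_overlap` vs the atlas mask), `visitation` (DWI grid),
#'   `streamlines`, and `rejections` (reason tally).
#' @export
run_tract_recipe <- function(recipe, field, params = tracking_params(),
                             structural_grid = NULL) {
  if (is.null(recipe$xfm)) stop("recipe is missing the DWI<->structural transform")
  structural_grid <- structural_grid %||% recipe$atlas_mask
  if (is.null(structural_grid)) stop("recipe needs a structural grid or atlas mask")
  dwi_grid <- list(data = field$fa, affine = field$affine)
  to_struct <- recipe$xfm                      # DWI world -> structural world
  to_dwi <- invert_transform(to_struct)
  seed_d <- resample_mask(recipe$seed, to_dwi, dwi_grid)
  wps_d <- lapply(recipe$waypoints %||% list(), resample_mask,
                  t = to_dwi, target = dwi_grid)
  res <- track(field, seed_d, wps_d, params)
  back <- resample_counts(res$visitation$counts, field$affine, to_struct,
                          structural_grid)
  vm_struct <- structure(list(counts = back,
                              total_samples = res$visitation$total_samples,
                              affine = structural_grid$affine),
                         class = "stem_vmap")
  tract <- threshold_map(vm_struct, frac = recipe$threshold_frac %||% 0.1)
  ov <- if (!is.null(recipe$atlas_mask) &&
            (any(tract$data) || any(recipe$atlas_mask$data)))
    overlap(tract, recipe$atlas_mask) else NULL
  list(tract_mask = tract, overlap = ov, visitation = res$visitation,
       streamlines = res$streamlines,
       rejections = table(res$streamlines$reason))
}
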