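#' Image volume container
#'
#' A `stem_volume` holds a 3D (or 4D, for diffusion-weighted series) scalar
#' grid together with a 4x4 voxel-to-world affine. World coordinates are RAS
#' millimetres; voxel indices are 0-based, so the affine maps the homogeneous
#' index `(i, j, k, 1)` of the first voxel `(0,0,0)` to the world position of
#' its centre. 4D volumes may carry per-frame b-values and unit gradient
#' vectors (`bvals`, `bvecs`) for tensor fitting.
#'
#' @param data numeric array, 3D or 4D.
#' @param affine invertible 4x4 voxel-to-world matrix (last row 0 0 0 1).
#' @param bvals optional numeric vector, one b-value (s/mm^2) per 4D frame.
#' @param bvecs optional 3-row or 3-column matrix of unit gradient vectors.
#' @return An object of class `stem_volume`.
#' @export
as_volume <- function(data, affine = diag(4), bvals = NULL, bvecs = NULL) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop("volume data must be 3D or 4D")
  if (any(dim(data) < 1L)) stop("every axis must have extent >= 1")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-10)
    stop("affine last row must be (0, 0, 0, 1)")
  v <- structure(list(data = data, affine = affine), class = "stem_volume")
  if (!is.null(bvals)) v <- set_gradients(v, bvals, bvecs)
  v
}

#' @export
print.stem_volume <- function(x, ...) {
  cat("<stem_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, voxel size ",
      paste(signif(voxel_size(x), 4), collapse = " x "), " mm\n", sep = "")
  if (!is.null(x$bvals))
    cat("  DWI series: ", sum(x$bvals > 0), " diffusion-weighted + ",
        sum(x$bvals == 0), " b0 frames\n", sep = "")
  invisible(x)
}

#' @rdname as_volume
#' @param v a `stem_volume`.
#' @export
voxel_size <- function(v) {
  L <- v$affine[1:3, 1:3]
  sqrt(colSums(L^2))
}

vol_dim <- function(v) dim(v$data)[1:3]

#' Attach diffusion gradient metadata to a 4D volume
#'
#' Validates that the gradient table matches the number of frames and that
#' all diffusion-weighted (`b > 0`) directions are unit vectors.
#'
#' @inheritParams as_volume
#' @param v a 4D `stem_volume`.
#' @return `v` with `bvals` (numeric) and `bvecs` (n x 3, unit rows) set.
#' @export
set_gradients <- function(v, bvals, bvecs) {
  if (length(dim(v$data)) != 4L)
    stop("gradient metadata applies to 4D volumes only")
  nfr <- dim(v$data)[4]
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) != 3L) bvecs <- t(bvecs)
  if (length(bvals) != nfr || nrow(bvecs) != nfr)
    stop("metadata error: bvals/bvecs count (", length(bvals), "/",
         nrow(bvecs), ") does not match frame count (", nfr, ")")
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- bvals > 0 & abs(nrm - 1) > 1e-3
  if (any(bad))
    stop("metadata error: non-unit gradient vector(s) at frame(s) ",
         paste(which(bad), collapse = ", "), " (norm ",
         paste(signif(nrm[bad], 4), collapse = ", "), ")")
  v$bvals <- bvals
  v$bvecs <- bvecs
  v
}

#' Read a volume from disk
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`) or Analyze 7.5 (`.hdr`/`.img`,
#' read-only) images. For a 4D diffusion series, pass the paths of
#' FSL-style `bvals`/`bvecs` sidecars (whitespace-separated rows); the
#' frame count must match and diffusion-weighted directions must be unit
#' vectors.
#'
#' @param path image file path.
#' @param bvals,bvecs optional paths to FSL gradient-table text files.
#' @return A `stem_volume`.
#' @export
read_volume <- function(path, bvals = NULL, bvecs = NULL) {
  if (!file.exists(path) && !file.exists(paste0(path, ".hdr")))
    stop("no such file: ", path)
  if (grepl("\\.(hdr|img)(\\.gz)?$", path) ||
      (!grepl("\\.nii(\\.gz)?$", path) && file.exists(sub("\\.[^.]*$", ".hdr", path)))) {
    stem <- sub("\\.(hdr|img)(\\.gz)?$", "", path)
    img <- tryCatch(oro.nifti::readANALYZE(stem),
                    error = function(e) stop("format error reading Analyze header: ",
                                             conditionMessage(e)))
    dat <- img@.Data
    pix <- img@pixdim[2:4]
    aff <- diag(c(pix, 1))                    # Analyze has no sform; axis-aligned
  } else {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("format error reading NIfTI: ",
                                             conditionMessage(e)))
    dat <- as.array(img)
    aff <- structure(RNifti::xform(img), class = NULL, code = NULL)
  }
  v <- as_volume(dat, aff)
  if (!is.null(bvals) || !is.null(bvecs)) {
    if (is.null(bvals) || is.null(bvecs))
      stop("metadata error: bvals and bvecs must be given together")
    v <- set_gradients(v, read_gradient_file(bvals), read_gradient_file(bvecs))
  }
  v
}

read_gradient_file <- function(path) {
  rows <- utils::read.table(path, header = FALSE)
  m <- as.matrix(rows)
  if (nrow(m) == 1L) as.numeric(m) else m
}

#' Write a volume (or mask) to a NIfTI-1 file
#'
#' @param v a `stem_volume` or `stem_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param bvals,bvecs optional paths for FSL gradient-table sidecars.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, bvals = NULL, bvecs = NULL) {
  dat <- if (inherits(v, "stem_mask")) array(as.numeric(v$data), dim(v$data)) else v$data
  img <- RNifti::asNifti(dat)
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path)
  if (!is.null(bvals) && !is.null(v$bvals)) {
    writeLines(paste(format(v$bvals, trim = TRUE), collapse = " "), bvals)
  }
  if (!is.null(bvecs) && !is.null(v$bvecs)) {
    writeLines(apply(t(v$bvecs), 1, paste, collapse = " "), bvecs)
  }
  invisible(path)
}

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 0-based and may be fractional; both functions accept
#' and return n x 3 matrices (single points may be plain length-3 vectors).
#'
#' @param v a `stem_volume` or `stem_mask`.
#' @param ijk,xyz n x 3 matrix of voxel indices / world coordinates (mm).
#' @return n x 3 matrix.
#' @export
voxel_to_world <- function(v, ijk) {
  ijk <- rbind3(ijk)
  t(v$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(v, xyz) {
  xyz <- rbind3(xyz)
  t(solve(v$affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

rbind3 <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
}

#' Crop a volume to a voxel-index box
#'
#' Boxes are half-open in 0-based voxel indices: voxel `i` is retained when
#' `lo[a] <= i < hi[a]` on every axis `a`. The affine of the result is
#' translated so retained voxels keep their world coordinates exactly.
#'
#' @param v a `stem_volume`.
#' @param lo,hi integer length-3 vectors, 0-based half-open bounds.
#' @return Cropped `stem_volume`.
#' @export
crop_box <- function(v, lo, hi) {
  d <- vol_dim(v)
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (any(lo < 0L) || any(hi > d) || any(hi <= lo))
    stop("empty or out-of-range crop box")
  idx <- lapply(1:3, function(a) (lo[a] + 1L):hi[a])
  dat <- if (length(dim(v$data)) == 4L)
    v$data[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  else
    v$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  aff <- v$affine
  aff[, 4] <- v$affine %*% c(lo, 1)
  out <- as_volume(dat, aff)
  out$bvals <- v$bvals; out$bvecs <- v$bvecs
  out
}

# Vectorized trilinear interpolation of a 3D array at fractional 0-based
# voxel coordinates. Points outside the grid return `outside`.
interp_trilinear <- function(arr, ijk, outside = 0) {
  d <- dim(arr)
  ijk <- rbind3(ijk)
  n <- nrow(ijk)
  i0 <- floor(ijk)
  f <- ijk - i0
  ok <- ijk[, 1] >= 0 & ijk[, 1] <= d[1] - 1 &
        ijk[, 2] >= 0 & ijk[, 2] <= d[2] - 1 &
        ijk[, 3] >= 0 & ijk[, 3] <= d[3] - 1
  out <- rep(outside, n)
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]; f <- f[ok, , drop = FALSE]
  # clamp upper corner so points exactly on the far face interpolate cleanly
  i1 <- pmin(i0 + 1, matrix(rep(d - 1, each = nrow(i0)), ncol = 3))
  at <- function(ii, jj, kk) arr[cbind(ii + 1L, jj + 1L, kk + 1L)]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  val <-
    at(i0[,1], i0[,2], i0[,3]) * (1-fx)*(1-fy)*(1-fz) +
    at(i1[,1], i0[,2], i0[,3]) *    fx *(1-fy)*(1-fz) +
    at(i0[,1], i1[,2], i0[,3]) * (1-fx)*   fy *(1-fz) +
    at(i1[,1], i1[,2], i0[,3]) *    fx *   fy *(1-fz) +
    at(i0[,1], i0[,2], i1[,3]) * (1-fx)*(1-fy)*   fz  +
    at(i1[,1], i0[,2], i1[,3]) *    fx *(1-fy)*   fz  +
    at(i0[,1], i1[,2], i1[,3]) * (1-fx)*   fy *   fz  +
    at(i1[,1], i1[,2], i1[,3]) *    fx *   fy *   fz
  out[ok] <- val
  out
}

#' Sample a volume at world coordinates
#'
#' Trilinear interpolation; points outside the grid return `outside`.
#'
#' @param v a `stem_volume`.
#' @param xyz n x 3 world coordinates (mm).
#' @param outside fill value for out-of-grid points.
#' @return numeric vector of length n.
#' @export
sample_volume <- function(v, xyz, outside = 0) {
  interp_trilinear(v$data, world_to_voxel(v, xyz), outside = outside)
}

#' Reslice a volume into AC-PC-aligned coronal planes
#'
#' Builds an orthonormal frame whose slice axis runs along the line from the
#' posterior commissure (PC) to the anterior commissure (AC), with origin at
#' the AC, and resamples the input by trilinear interpolation onto an
#' isotropic grid of the requested spacing covering the input field of view.
#' Coronal slice positions are signed millimetres from the AC (positive
#' anterior), available via [slice_positions()].
#'
#' @param v a 3D `stem_volume`.
#' @param ac,pc world coordinates (mm) of the anterior / posterior commissure.
#' @param spacing output voxel size in mm (isotropic).
#' @return A `stem_volume` whose second voxel axis is the AC-PC direction.
#' @export
reslice_coronal <- function(v, ac, pc, spacing) {
  ac <- as.numeric(ac); pc <- as.numeric(pc)
  if (sqrt(sum((ac - pc)^2)) < 1e-9) stop("geometry error: ac == pc")
  if (spacing <= 0) stop("spacing must be positive")
  e_ap <- (ac - pc) / sqrt(sum((ac - pc)^2))     # anterior
  up <- c(0, 0, 1)
  if (abs(sum(up * e_ap)) > 0.99) up <- c(0, 1, 0)
  e_lr <- cross3(e_ap, up); e_lr <- e_lr / sqrt(sum(e_lr^2))   # right
  e_si <- cross3(e_lr, e_ap)                                    # superior
  R <- cbind(e_lr, e_ap, e_si)                   # new-frame axes in world
  # corners of the input volume in the new frame (coordinates relative to AC)
  d <- vol_dim(v)
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                   c(0, d[3] - 1)))
  cw <- voxel_to_world(v, corners)
  loc <- sweep(cw, 2, ac) %*% R                  # n x 3 in (lr, ap, si)
  lo <- apply(loc, 2, min); hi <- apply(loc, 2, max)
  n <- pmax(2L, as.integer(floor((hi - lo) / spacing)) + 1L)
  # grid origin chosen so AC (frame coordinate 0) falls exactly on a voxel
  # centre along every axis
  orig <- spacing * floor(lo / spacing)
  aff <- diag(4)
  aff[1:3, 1:3] <- R * spacing
  aff[1:3, 4] <- ac + R %*% orig
  g <- as.matrix(expand.grid(i = 0:(n[1] - 1), j = 0:(n[2] - 1),
                             k = 0:(n[3] - 1)))
  world <- t(aff %*% rbind(t(g), 1))[, 1:3]
  vals <- sample_volume(v, world)
  out <- as_volume(array(vals, n), aff)
  attr(out, "ac_world") <- ac
  out
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Coronal slice positions of a resliced volume
#'
#' @param v a `stem_volume` produced by [reslice_coronal()].
#' @return signed mm of each coronal slice from the AC (positive anterior).
#' @export
slice_positions <- function(v) {
  n <- vol_dim(v)[2]
  ref <- attr(v, "ac_world") %||% as.numeric(voxel_to_world(v, c(0, 0, 0)))
  dir <- v$affine[1:3, 2] / sqrt(sum(v$affine[1:3, 2]^2))
  pos <- voxel_to_world(v, cbind(0, 0:(n - 1), 0))
  as.numeric(sweep(pos, 2, ref) %*% dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract one coronal slice as an in-plane point grid
#'
#' Returns the slice image plus the in-plane mm coordinates of its pixels
#' (axes: left-right and inferior-superior for a coronal volume).
#'
#' @param v a `stem_volume` with slice axis 2 (see [reslice_coronal()]).
#' @param j fractional 0-based slice index along axis 2; non-integer values
#'   are interpolated trilinearly.
#' @return list with `image` (matrix), `x`, `z` (in-plane mm axes),
#'   `position` (0-based index used).
#' @export
extract_slice <- function(v, j) {
  d <- vol_dim(v)
  if (j < 0 || j > d[2] - 1) stop("slice index out of range")
  g <- as.matrix(expand.grid(i = 0:(d[1] - 1), k = 0:(d[3] - 1)))
  ijk <- cbind(g[, 1], j, g[, 2])
  vals <- interp_trilinear(v$data, ijk)
  px <- voxel_to_world(v, cbind(0:(d[1] - 1), j, 0))
  pz <- voxel_to_world(v, cbind(0, j, 0:(d[3] - 1)))
  list(image = matrix(vals, d[1], d[3]),
       x = px[, 1], z = pz[, 3], position = j)
}
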