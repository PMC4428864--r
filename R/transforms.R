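#' Affine world-to-world transforms
#'
#' A `stem_xfm` wraps a 4x4 homogeneous matrix mapping world coordinates of
#' one space to another (e.g. SWI to DWI), tagged with its degrees of
#' freedom. For `dof = 7` the linear part is a single global scale times a
#' rotation.
#'
#' @param matrix 4x4 homogeneous matrix, last row `(0, 0, 0, 1)`.
#' @param dof degrees of freedom tag: 6, 7, 9 or 12.
#' @return A `stem_xfm`.
#' @export
as_xfm <- function(matrix, dof = 12L) {
  m <- as.matrix(matrix)
  if (!all(dim(m) == c(4L, 4L))) stop("transform matrix must be 4x4")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-8)
    stop("transform last row must be (0, 0, 0, 1)")
  if (abs(det(m)) < .Machine$double.eps) stop("transform must be invertible")
  if (!dof %in% c(6L, 7L, 9L, 12L)) stop("dof must be 6, 7, 9 or 12")
  structure(list(matrix = m, dof = as.integer(dof)), class = "stem_xfm")
}

#' @export
print.stem_xfm <- function(x, ...) {
  cat("<stem_xfm> dof =", x$dof, "\n")
  print(signif(x$matrix, 6))
  invisible(x)
}

#' Least-squares similarity transform from matched point pairs
#'
#' Closed-form orthogonal-Procrustes fit (Umeyama / Kabsch) of the rigid
#' (`dof = 6`) or similarity (`dof = 7`: rotation, translation and one
#' global scale) transform minimizing the sum of squared residuals
#' `sum(|T(src_i) - dst_i|^2)`. This realizes the transform contract of a
#' 7-DOF cross-modality alignment when landmark correspondences are known.
#'
#' @param src,dst n x 3 matrices of matched world points (n >= 3,
#'   non-collinear).
#' @param dof 6 (rigid) or 7 (rigid + global scale).
#' @return A `stem_xfm` with residual RMS in attribute `rms`.
#' @export
estimate_similarity_transform <- function(src, dst, dof = 7L) {
  src <- rbind3(src); dst <- rbind3(dst)
  if (nrow(src) != nrow(dst)) stop("src and dst must pair up")
  if (nrow(src) < 3L) stop("need at least 3 point pairs")
  if (!dof %in% c(6L, 7L)) stop("dof must be 6 or 7")
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  S <- sweep(src, 2, mu_s); D <- sweep(dst, 2, mu_d)
  var_s <- sum(S^2) / nrow(S)
  C <- crossprod(D, S) / nrow(S)          # 3x3 covariance dst~src
  sv <- svd(C)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("rank error: point pairs are collinear or coincident")
  sgn <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% sgn %*% t(sv$v)
  s <- if (dof == 7L) sum(diag(sgn) * sv$d) / var_s else 1
  if (s <= 0) stop("rank error: degenerate configuration (non-positive scale)")
  m <- diag(4)
  m[1:3, 1:3] <- s * R
  m[1:3, 4] <- mu_d - s * R %*% mu_s
  out <- as_xfm(m, dof)
  res <- apply_transform(out, src) - dst
  attr(out, "rms") <- sqrt(mean(rowSums(res^2)))
  out
}

#' Apply / invert an affine transform
#'
#' @param t a `stem_xfm`.
#' @param points n x 3 matrix (or length-3 vector) of world points.
#' @return `apply_transform`: n x 3 matrix of mapped points.
#'   `invert_transform`: the inverse `stem_xfm`.
#' @export
apply_transform <- function(t, points) {
  p <- rbind3(points)
  t(t$matrix %*% rbind(base::t(p), 1))[, 1:3, drop = FALSE]
}

#' @rdname apply_transform
#' @export
invert_transform <- function(t) {
  as_xfm(solve(t$matrix), t$dof)
}

#' Read / write a FLIRT-style plain-text 4x4 matrix
#'
#' Row-major, whitespace-separated, four numbers per line.
#'
#' @param path text file path.
#' @param dof dof tag to attach on read.
#' @return `read_flirt_matrix`: a `stem_xfm`; `write_flirt_matrix`: `path`.
#' @export
read_flirt_matrix <- function(path, dof = 12L) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  as_xfm(m, dof)
}

#' @rdname read_flirt_matrix
#' @param t a `stem_xfm`.
#' @export
write_flirt_matrix <- function(t, path) {
  writeLines(apply(t$matrix, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), path)
  invisible(path)
}

#' Binary mask on a volume grid
#'
#' A `stem_mask` is a logical grid sharing dims and affine with its
#' reference volume, tagged with a role (`seed`, `waypoint`, `region` or
#' `exclusion`).
#'
#' @param data logical/numeric 3D array (nonzero = in mask).
#' @param affine 4x4 voxel-to-world matrix.
#' @param role one of `"seed"`, `"waypoint"`, `"region"`, `"exclusion"`.
#' @param label optional region label.
#' @return A `stem_mask`.
#' @export
as_mask <- function(data, affine = diag(4), role = "region", label = NULL) {
  role <- match.arg(role, c("seed", "waypoint", "region", "exclusion"))
  data <- array(as.logical(data) & !is.na(data), dim(as.array(data)))
  if (length(dim(data)) != 3L) stop("mask must be 3D")
  if (role == "seed" && !any(data)) stop("seed mask must be nonempty")
  structure(list(data = data, affine = as.matrix(affine), role = role,
                 label = label), class = "stem_mask")
}

#' @export
print.stem_mask <- function(x, ...) {
  cat("<stem_mask> role=", x$role,
      if (!is.null(x$label)) paste0(" label=", x$label),
      ", ", sum(x$data), "/", length(x$data), " voxels set\n", sep = "")
  invisible(x)
}

#' Read a binary mask from a NIfTI file
#'
#' @inheritParams read_volume
#' @inheritParams as_mask
#' @export
read_mask <- function(path, role = "region", label = NULL) {
  v <- read_volume(path)
  as_mask(v$data > 0.5, v$affine, role = role, label = label)
}

#' Resample a mask onto another grid through a world transform
#'
#' Nearest-neighbour resampling (binary masks stay binary): each target
#' voxel centre is mapped back through `invert(t)` into the source space
#' and takes the value of the nearest source voxel. An empty result is
#' permitted but raises a warning.
#'
#' @param m a `stem_mask` on the source grid.
#' @param t a `stem_xfm` mapping source world coordinates to target world
#'   coordinates (identity by default).
#' @param target a `stem_volume` or `stem_mask` defining the output grid.
#' @return A `stem_mask` on the target grid (same role/label).
#' @export
resample_mask <- function(m, t = as_xfm(diag(4)), target) {
  d <- dim(target$data)[1:3]
  g <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                             k = 0:(d[3] - 1)))
  world_t <- t(target$affine %*% rbind(base::t(g), 1))[, 1:3]
  world_s <- apply_transform(invert_transform(t), world_t)
  ijk <- round(t(solve(m$affine) %*% rbind(base::t(world_s), 1))[, 1:3])
  ds <- dim(m$data)
  ok <- ijk[, 1] >= 0 & ijk[, 1] < ds[1] &
        ijk[, 2] >= 0 & ijk[, 2] < ds[2] &
        ijk[, 3] >= 0 & ijk[, 3] < ds[3]
  val <- logical(nrow(g))
  val[ok] <- m$data[ijk[ok, , drop = FALSE] + 1L]
  if (!any(val))
    warning("resampled mask is empty", call. = FALSE)
  out <- array(val, d)
  res <- structure(list(data = out, affine = as.matrix(target$affine),
                        role = m$role, label = m$label), class = "stem_mask")
  res
}
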