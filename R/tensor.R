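#' Fit a per-voxel diffusion tensor orientation field
#'
#' Log-linear least-squares single-tensor fit: for each voxel the model
#' `log S = log S0 - b g' D g` is solved by ordinary least squares over all
#' frames, the principal eigenvector of `D` gives the local fiber
#' direction, and fractional anisotropy (FA) the anisotropy scalar. The
#' angular concentration of the Watson distribution used by the
#' probabilistic tracker grows with anisotropy: `kappa = kappa0 * FA`, so
#' orientation uncertainty widens as anisotropy falls.
#'
#' @param dwi 4D `stem_volume` with gradient metadata (or pass
#'   `bvals`/`bvecs`).
#' @param bvals,bvecs optional gradient table overriding the volume's.
#' @param kappa0 concentration at FA = 1 (default 60).
#' @return A `stem_field`: arrays `dir` (x,y,z,3 unit principal
#'   directions), `fa`, `kappa`, `evals` (x,y,z,3 eigenvalues, descending),
#'   and the volume `affine`. Voxels with non-positive b0 signal are
#'   flagged background (`fa = 0`).
#' @export
fit_tensor_field <- function(dwi, bvals = NULL, bvecs = NULL, kappa0 = 60) {
  bvals <- bvals %||% dwi$bvals
  bvecs <- bvecs %||% dwi$bvecs
  if (is.null(bvals) || is.null(bvecs))
    stop("gradient table (bvals/bvecs) required")
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) != 3L) bvecs <- t(bvecs)
  nfr <- dim(dwi$data)[4]
  if (length(bvals) != nfr) stop("bvals length must match frame count")
  if (nfr < 7L || !any(bvals == 0))
    stop("need >= 7 frames including >= 1 b0")
  g <- bvecs
  # design: log S = beta0 - b * (gx^2 Dxx + gy^2 Dyy + gz^2 Dzz
  #                              + 2 gx gy Dxy + 2 gx gz Dxz + 2 gy gz Dyz)
  X <- cbind(1, -bvals * g[, 1]^2, -bvals * g[, 2]^2, -bvals * g[, 3]^2,
             -2 * bvals * g[, 1] * g[, 2], -2 * bvals * g[, 1] * g[, 3],
             -2 * bvals * g[, 2] * g[, 3])
  if (qr(X)$rank < 7L)
    stop("gradient directions do not span 3D (rank-deficient design)")
  d <- dim(dwi$data)[1:3]
  nvox <- prod(d)
  S <- matrix(dwi$data, nvox, nfr)
  s0 <- rowMeans(S[, bvals == 0, drop = FALSE])
  bg <- !(s0 > 0) | apply(S <= 0, 1, any)
  fa <- numeric(nvox)
  kap <- numeric(nvox)
  dirs <- matrix(0, nvox, 3)
  evals <- matrix(0, nvox, 3)
  fg <- which(!bg)
  if (length(fg)) {
    Y <- log(t(S[fg, , drop = FALSE]))            # nfr x nfg
    beta <- solve(crossprod(X), crossprod(X, Y))  # 7 x nfg
    for (m in seq_along(fg)) {
      b <- beta[, m]
      D <- matrix(c(b[2], b[5], b[6],
                    b[5], b[3], b[7],
                    b[6], b[7], b[4]), 3, 3)
      e <- eigen(D, symmetric = TRUE)
      lam <- e$values
      evals[fg[m], ] <- lam
      md <- mean(lam)
      den <- sum(lam^2)
      f <- if (den > 0) sqrt(1.5 * sum((lam - md)^2) / den) else 0
      fa[fg[m]] <- min(max(f, 0), 1)
      dirs[fg[m], ] <- e$vectors[, 1]
    }
    kap[fg] <- kappa0 * fa[fg]
  }
  structure(list(dir = array(dirs, c(d, 3)), fa = array(fa, d),
                 kappa = array(kap, d), evals = array(evals, c(d, 3)),
                 affine = dwi$affine, kappa0 = kappa0),
            class = "stem_field")
}

#' @export
print.stem_field <- function(x, ...) {
  cat("<stem_field> ", paste(dim(x$fa), collapse = " x "),
      " voxels, FA range ", paste(signif(range(x$fa), 3), collapse = "-"),
      ", kappa0 = ", x$kappa0, "\n", sep = "")
  invisible(x)
}

#' Closed-form fractional anisotropy from eigenvalues
#'
#' @param lam length-3 vector (or n x 3 matrix) of tensor eigenvalues.
#' @return FA in `[0, 1]`.
#' @export
fa_from_eigenvalues <- function(lam) {
  lam <- rbind3(lam)
  md <- rowMeans(lam)
  f <- sqrt(1.5 * rowSums((lam - md)^2) / rowSums(lam^2))
  f[!is.finite(f)] <- 0
  pmin(1, pmax(0, f))
}
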