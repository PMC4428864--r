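#' Ordered stack of per-slice contours
#'
#' Holds, for one region label, the closed 2D contour of the region on each
#' coronal slice together with the slice position (mm). Positions must be
#' strictly monotone and each slice carries exactly one simple contour
#' (branching topology is out of scope).
#'
#' @param label region label.
#' @param positions numeric vector of slice positions (mm), strictly
#'   monotone.
#' @param contours list of n x 2 contour matrices (implicit closure).
#' @return A `stem_stack`.
#' @export
contour_stack <- function(label, positions, contours) {
  positions <- as.numeric(positions)
  if (length(positions) < 2L) stop("a contour stack needs >= 2 slices")
  if (length(contours) != length(positions))
    stop("one contour per slice position required")
  if (!(all(diff(positions) > 0) || all(diff(positions) < 0)))
    stop("slice positions must be strictly monotone (crossing slices)")
  if (positions[1] > positions[length(positions)]) {
    positions <- rev(positions); contours <- rev(contours)
  }
  contours <- lapply(contours, function(cc) {
    cc <- as.matrix(cc)
    if (nrow(cc) > 1L && max(abs(cc[1, ] - cc[nrow(cc), ])) < 1e-12)
      cc <- cc[-nrow(cc), , drop = FALSE]
    if (nrow(cc) < 3L) stop("each contour needs >= 3 vertices")
    cc
  })
  structure(list(label = label, positions = positions, contours = contours),
            class = "stem_stack")
}

# signed polygon area (shoelace); positive = counterclockwise
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(2:nrow(p), 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Resample a closed contour to n points
#'
#' Uniform arc-length spacing, counterclockwise orientation enforced, and a
#' deterministic correspondence convention: the output is rotated so its
#' first vertex has the minimum polar angle about the contour centroid.
#'
#' @param contour m x 2 closed polyline (implicit closure).
#' @param n number of output vertices (>= 3).
#' @return n x 2 matrix.
#' @export
resample_contour <- function(contour, n) {
  if (n < 3L) stop("n must be >= 3")
  p <- as.matrix(contour)
  if (nrow(p) > 1L && max(abs(p[1, ] - p[nrow(p), ])) < 1e-12)
    p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) < 3L) stop("contour needs >= 3 distinct vertices")
  if (polygon_area(p) < 0) p <- p[nrow(p):1, , drop = FALSE]
  seg <- sqrt(rowSums((p[c(2:nrow(p), 1), , drop = FALSE] - p)^2))
  per <- sum(seg)
  if (per < 1e-12) stop("zero-perimeter contour")
  cum <- c(0, cumsum(seg))                    # arc length at each vertex
  s <- (0:(n - 1)) / n * per
  seg_idx <- findInterval(s, cum, rightmost.closed = TRUE)
  frac <- (s - cum[seg_idx]) / seg[seg_idx]
  nxt <- c(2:nrow(p), 1)
  out <- p[seg_idx, , drop = FALSE] +
    (p[nxt[seg_idx], , drop = FALSE] - p[seg_idx, , drop = FALSE]) * frac
  ctr <- colMeans(out)
  ang <- atan2(out[, 2] - ctr[2], out[, 1] - ctr[1])
  k <- which.min(ang)
  out[c(k:n, seq_len(k - 1L)), , drop = FALSE]
}

#' Triangle surface mesh
#'
#' @param vertices V x 3 matrix of world coordinates (mm).
#' @param faces F x 3 matrix of 1-based vertex indices, consistently
#'   oriented.
#' @param label region label.
#' @return A `stem_mesh`.
#' @export
as_mesh <- function(vertices, faces, label = NULL) {
  structure(list(vertices = as.matrix(vertices),
                 faces = matrix(as.integer(as.matrix(faces)), ncol = 3),
                 label = label), class = "stem_mesh")
}

#' @export
print.stem_mesh <- function(x, ...) {
  cat("<stem_mesh>", if (!is.null(x$label)) x$label, nrow(x$vertices),
      "vertices,", nrow(x$faces), "faces, volume",
      signif(mesh_volume(x), 5), "mm^3\n")
  invisible(x)
}

#' Loft a contour stack into a watertight triangle mesh
#'
#' Each contour is resampled to `n` corresponding vertices
#' ([resample_contour()]); adjacent rings are joined point-to-point into
#' triangle strips and the end contours are capped with centroid fans.
#' In-plane contour axes map to world x and z; the slice position is the
#' world y (anteroposterior) coordinate. The result is audited for
#' watertightness and oriented with positive enclosed volume.
#'
#' @param stack a `stem_stack`.
#' @param n vertices per ring (default 128).
#' @return A `stem_mesh`.
#' @export
loft <- function(stack, n = 128L) {
  stopifnot(inherits(stack, "stem_stack"))
  ns <- length(stack$positions)
  rings <- lapply(stack$contours, resample_contour, n = n)
  verts <- do.call(rbind, lapply(seq_len(ns), function(s)
    cbind(rings[[s]][, 1], stack$positions[s], rings[[s]][, 2])))
  c0 <- c(mean(rings[[1]][, 1]), stack$positions[1], mean(rings[[1]][, 2]))
  cT <- c(mean(rings[[ns]][, 1]), stack$positions[ns], mean(rings[[ns]][, 2]))
  verts <- rbind(verts, c0, cT)
  i0 <- ns * n + 1L; iT <- ns * n + 2L
  faces <- vector("list", ns + 1L)
  idx <- function(s, i) (s - 1L) * n + ((i - 1L) %% n) + 1L
  ii <- seq_len(n); jj <- ii %% n + 1L
  for (s in seq_len(ns - 1L)) {
    a_i <- idx(s, ii); a_j <- idx(s, jj)
    b_i <- idx(s + 1L, ii); b_j <- idx(s + 1L, jj)
    faces[[s]] <- rbind(cbind(a_i, a_j, b_j), cbind(a_i, b_j, b_i))
  }
  faces[[ns]] <- cbind(i0, idx(1L, jj), idx(1L, ii))        # bottom cap
  faces[[ns + 1L]] <- cbind(iT, idx(ns, ii), idx(ns, jj))   # top cap
  m <- as_mesh(verts, do.call(rbind, faces), label = stack$label)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  audit <- watertight_audit(m)
  if (!audit$watertight)
    stop("lofted mesh failed watertightness audit: ", audit$reason)
  m
}

#' Watertightness audit
#'
#' Checks that no face is degenerate and that every undirected edge is
#' shared by exactly two faces with opposite direction (closed, consistently
#' oriented 2-manifold).
#'
#' @param m a `stem_mesh`.
#' @return list with `watertight` (logical) and `reason`.
#' @export
watertight_audit <- function(m) {
  f <- m$faces
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    return(list(watertight = FALSE, reason = "degenerate face"))
  from <- c(f[, 1], f[, 2], f[, 3])
  to   <- c(f[, 2], f[, 3], f[, 1])
  dir_key <- paste(from, to)
  if (anyDuplicated(dir_key))
    return(list(watertight = FALSE, reason = "duplicated directed edge"))
  und_key <- paste(pmin(from, to), pmax(from, to))
  cnt <- table(und_key)
  if (any(cnt != 2L))
    return(list(watertight = FALSE,
                reason = "edge not shared by exactly 2 faces"))
  list(watertight = TRUE, reason = "ok")
}

#' Signed enclosed volume of a mesh (mm^3)
#'
#' Sum of signed tetrahedron volumes against the origin; positive for
#' outward-oriented watertight meshes.
#'
#' @param m a `stem_mesh`.
#' @return numeric scalar.
#' @export
mesh_volume <- function(m) {
  v1 <- m$vertices[m$faces[, 1], , drop = FALSE]
  v2 <- m$vertices[m$faces[, 2], , drop = FALSE]
  v3 <- m$vertices[m$faces[, 3], , drop = FALSE]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
      v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
      v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

#' Voxelize a watertight mesh onto a volume grid
#'
#' Parity (ray-crossing) rule: a voxel is set when its centre lies inside
#' the mesh, with rays cast along the third voxel axis in index space.
#' Ray origins carry a fixed sub-voxel offset so rays never hit mesh edges
#' exactly, making the result deterministic; voxel centres lying on the
#' surface are counted inside.
#'
#' @param m a `stem_mesh` (must pass [watertight_audit()]).
#' @param grid a `stem_volume` or `stem_mask` defining the output grid.
#' @return A `stem_mask` (role `region`, label from the mesh).
#' @export
voxelize <- function(m, grid) {
  audit <- watertight_audit(m)
  if (!audit$watertight) stop("non-watertight mesh: ", audit$reason)
  d <- dim(grid$data)[1:3]
  A <- as.matrix(grid$affine)
  vi <- t(solve(A) %*% rbind(t(m$vertices), 1))[, 1:3]    # index space
  eps_i <- 1e-6; eps_j <- 2.3e-6                          # ray jitter
  tri <- m$faces
  cols <- integer(0); ks <- numeric(0)
  for (t in seq_len(nrow(tri))) {
    v <- vi[tri[t, ], , drop = FALSE]
    ilo <- ceiling(min(v[, 1]) - eps_i); ihi <- floor(max(v[, 1]) - eps_i)
    jlo <- ceiling(min(v[, 2]) - eps_j); jhi <- floor(max(v[, 2]) - eps_j)
    if (ihi < ilo || jhi < jlo) next
    g <- as.matrix(expand.grid(i = ilo:ihi, j = jlo:jhi))
    lam <- barycentric(cbind(g[, 1] + eps_i, g[, 2] + eps_j),
                       v[, 1:2, drop = FALSE])
    if (any(!is.finite(lam))) next                        # ij-degenerate tri
    inside <- lam[, 1] >= 0 & lam[, 2] >= 0 & lam[, 3] >= 0
    if (!any(inside)) next
    kc <- lam[inside, , drop = FALSE] %*% v[, 3]
    cols <- c(cols, g[inside, 1] * d[2] + g[inside, 2])
    ks <- c(ks, kc)
  }
  out <- array(FALSE, d)
  if (length(cols)) {
    eps_k <- 1e-7
    for (col in unique(cols)) {
      kc <- ks[cols == col]
      i <- col %/% d[2]; j <- col %% d[2]
      if (i < 0 || i >= d[1] || j < 0 || j >= d[2]) next
      kvox <- 0:(d[3] - 1)
      below <- vapply(kvox, function(k) sum(kc < k + eps_k), numeric(1))
      above <- vapply(kvox, function(k) sum(kc > k - eps_k), numeric(1))
      out[i + 1L, j + 1L, (below %% 2 == 1) | (above %% 2 == 1)] <- TRUE
    }
  }
  structure(list(data = out, affine = A, role = "region", label = m$label),
            class = "stem_mask")
}

#' Volumetric overlap between two masks
#'
#' Reports exact intersection and union voxel counts, the Jaccard percent
#' `100 * |a & b| / |a | b|` (the headline number) and both asymmetric
#' fractions `100 * |a & b| / |a|` and `/ |b|`.
#'
#' @param a,b `stem_mask`s on the same grid.
#' @return A `stem_overlap` list: `label_a`, `label_b`, `n_intersection`,
#'   `n_union`, `jaccard_pct`, `frac_of_a_pct`, `frac_of_b_pct`.
#' @export
overlap <- function(a, b) {
  if (!all(dim(a$data) == dim(b$data)) ||
      max(abs(a$affine - b$affine)) > 1e-6)
    stop("grid mismatch between masks")
  na <- sum(a$data); nb <- sum(b$data)
  if (na == 0 && nb == 0) stop("overlap undefined: both masks empty")
  ni <- sum(a$data & b$data)
  nu <- sum(a$data | b$data)
  structure(list(label_a = a$label %||% "a", label_b = b$label %||% "b",
                 n_intersection = ni, n_union = nu,
                 jaccard_pct = 100 * ni / nu,
                 frac_of_a_pct = if (na > 0) 100 * ni / na else NA_real_,
                 frac_of_b_pct = if (nb > 0) 100 * ni / nb else NA_real_),
            class = "stem_overlap")
}

#' @export
print.stem_overlap <- function(x, ...) {
  cat("<stem_overlap> ", x$label_a, " vs ", x$label_b, ": Jaccard ",
      sprintf("%.2f%%", x$jaccard_pct), " (", x$n_intersection, "/",
      x$n_union, " voxels)\n", sep = "")
  invisible(x)
}

#' Export a mesh to PLY or OBJ
#'
#' @param m a `stem_mesh`.
#' @param path output file (`.ply` ASCII or `.obj`).
#' @export
write_mesh <- function(m, path) {
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(m$vertices)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(m$faces)),
                 "property list uchar int vertex_indices", "end_header"),
               con)
    utils::write.table(format(m$vertices, trim = TRUE, digits = 9), con,
                       row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    utils::write.table(cbind(3L, m$faces - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    v <- apply(m$vertices, 1, function(r)
      paste("v", paste(format(r, trim = TRUE, digits = 9), collapse = " ")))
    f <- apply(m$faces, 1, function(r)
      paste("f", paste(r, collapse = " ")))
    writeLines(c(v, f), path)
  } else stop("unsupported mesh format: ", path)
  invisible(path)
}
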