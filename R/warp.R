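#' Atlas plates and landmark pairs
#'
#' An atlas plate is a 2D coronal drawing at a known anteroposterior
#' position: named closed contours (region label -> ordered n x 2 vertex
#' matrix, in-plane mm) plus the landmark points used for warping.
#'
#' @param id plate identifier.
#' @param position_mm anteroposterior position, signed mm from the AC.
#' @param contours named list of n x 2 matrices (closed polylines; the
#'   closing edge from last vertex back to first is implicit).
#' @param landmarks m x 2 matrix of in-plane landmark points (m >= 3).
#' @return A `stem_plate`.
#' @export
atlas_plate <- function(id, position_mm, contours = list(), landmarks) {
  landmarks <- as.matrix(landmarks)
  if (ncol(landmarks) != 2L || nrow(landmarks) < 3L)
    stop("a plate needs >= 3 2D landmarks")
  contours <- lapply(contours, function(cc) {
    cc <- as.matrix(cc)
    # drop an explicit closing vertex; closure is implicit
    if (nrow(cc) > 1L && max(abs(cc[1, ] - cc[nrow(cc), ])) < 1e-12)
      cc <- cc[-nrow(cc), , drop = FALSE]
    cc
  })
  structure(list(id = id, position_mm = as.numeric(position_mm),
                 contours = contours, landmarks = landmarks),
            class = "stem_plate")
}

#' @export
print.stem_plate <- function(x, ...) {
  cat("<stem_plate> ", x$id, " @ ", signif(x$position_mm, 4), " mm, ",
      length(x$contours), " contour(s), ", nrow(x$landmarks),
      " landmarks\n", sep = "")
  invisible(x)
}

#' @rdname atlas_plate
#' @param src,dst m x 2 matrices of paired atlas-side / MRI-side landmarks
#'   in the same slice plane (mm).
#' @export
landmark_pairs <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (!all(dim(src) == dim(dst)) || ncol(src) != 2L)
    stop("src and dst must be matched m x 2 matrices")
  if (nrow(src) < 3L) stop("need >= 3 landmark pairs")
  if (!all(is.finite(src)) || !all(is.finite(dst)))
    stop("landmarks must be finite")
  structure(list(src = src, dst = dst), class = "stem_landmarks")
}

#' Read / write atlas plates as JSON
#'
#' Schema per plate: `id`, `position_mm`, `contours` (label -> array of
#' `[x, y]` vertices) and `landmarks` (array of `[x, y]`).
#'
#' @param plates list of `stem_plate`.
#' @param path JSON file path.
#' @export
write_plates <- function(plates, path) {
  payload <- lapply(plates, function(p) list(
    id = p$id, position_mm = p$position_mm,
    contours = lapply(p$contours, function(m) unname(as.matrix(m))),
    landmarks = unname(as.matrix(p$landmarks))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plates
#' @export
read_plates <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = TRUE)
  lapply(seq_along(payload), function(i) {
    p <- payload[[i]]
    atlas_plate(p$id, p$position_mm,
                contours = lapply(p$contours, as.matrix),
                landmarks = as.matrix(p$landmarks))
  })
}

# Delaunay triangulation of a 2D point set via deldir, with a deterministic
# 1e-9 jitter keyed to point index to break cocircular ties. Returns an
# ntri x 3 matrix of point indices.
delaunay_triangles <- function(pts) {
  n <- nrow(pts)
  idx <- seq_len(n)
  jx <- 1e-9 * cos(9898 * idx)
  jy <- 1e-9 * sin(7817 * idx)
  dd <- deldir::deldir(pts[, 1] + jx, pts[, 2] + jy, suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  if (length(tl) == 0L)
    stop("rank error: landmarks are collinear (no triangulation)")
  t(vapply(tl, function(tr) as.integer(tr$ptNum), integer(3)))
}

# 2x3 affine [M | b] mapping triangle s (3x2) onto triangle d (3x2)
triangle_affine <- function(s, d) {
  A <- cbind(s, 1)                         # 3x3
  if (abs(det(A)) < 1e-14 * max(1, max(abs(s)))^2)
    stop("rank error: degenerate (collinear) triangle")
  coef <- solve(A, d)                      # 3x2: rows (mx, my, b)
  t(coef)                                  # 2x3: [M | b] with b last column
}

#' Fit a piecewise-affine landmark warp
#'
#' Delaunay-triangulates the atlas-side landmarks and fits one affine map
#' per triangle carrying it onto the matched MRI-side triangle. The warp
#' interpolates every landmark pair exactly (zero residual) and is
#' continuous across shared edges — affine locally, nonlinear globally.
#' Points outside the landmark hull are mapped by the affine of the nearest
#' triangle.
#'
#' @param pairs a `stem_landmarks` object (>= 3 non-collinear atlas points,
#'   no duplicates).
#' @return A `stem_warp` with fields `src`, `dst`, `triangles` (ntri x 3
#'   indices) and `affines` (list of 2 x 3 `[M | b]` matrices).
#' @export
fit_warp <- function(pairs) {
  stopifnot(inherits(pairs, "stem_landmarks"))
  src <- pairs$src; dst <- pairs$dst
  dd <- as.matrix(stats::dist(src))
  diag(dd) <- Inf
  if (min(dd) < 1e-12) stop("duplicate atlas landmark points")
  tri <- delaunay_triangles(src)
  affs <- lapply(seq_len(nrow(tri)), function(t)
    triangle_affine(src[tri[t, ], , drop = FALSE],
                    dst[tri[t, ], , drop = FALSE]))
  structure(list(src = src, dst = dst, triangles = tri, affines = affs,
                 steps = NULL), class = "stem_warp")
}

#' @export
print.stem_warp <- function(x, ...) {
  if (is.null(x$steps))
    cat("<stem_warp> ", nrow(x$src), " landmarks, ", nrow(x$triangles),
        " triangles\n", sep = "")
  else
    cat("<stem_warp> fold-back composition of ", length(x$steps),
        " partial warps (", nrow(x$src), " landmarks)\n", sep = "")
  invisible(x)
}

# Barycentric coordinates of points p (n x 2) w.r.t. triangle v (3 x 2)
barycentric <- function(p, v) {
  T <- cbind(v[1, ] - v[3, ], v[2, ] - v[3, ])
  dt <- T[1, 1] * T[2, 2] - T[1, 2] * T[2, 1]
  rel <- sweep(p, 2, v[3, ])
  l1 <- (T[2, 2] * rel[, 1] - T[1, 2] * rel[, 2]) / dt
  l2 <- (-T[2, 1] * rel[, 1] + T[1, 1] * rel[, 2]) / dt
  cbind(l1, l2, 1 - l1 - l2)
}

# squared distance from points p (n x 2) to segment a-b
point_seg_dist2 <- function(p, a, b) {
  ab <- b - a
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / sum(ab^2)
  t <- pmin(1, pmax(0, t))
  dx <- a[1] + t * ab[1] - p[, 1]
  dy <- a[2] + t * ab[2] - p[, 2]
  dx^2 + dy^2
}

# index of the triangle containing (or nearest to) each point
locate_triangles <- function(w, pts) {
  n <- nrow(pts)
  hit <- rep(NA_integer_, n)
  for (t in seq_len(nrow(w$triangles))) {
    todo <- which(is.na(hit))
    if (!length(todo)) break
    lam <- barycentric(pts[todo, , drop = FALSE],
                       w$src[w$triangles[t, ], , drop = FALSE])
    inside <- rowSums(lam >= -1e-9) == 3L
    hit[todo[inside]] <- t
  }
  out <- which(is.na(hit))
  if (length(out)) {
    d2 <- matrix(Inf, length(out), nrow(w$triangles))
    for (t in seq_len(nrow(w$triangles))) {
      v <- w$src[w$triangles[t, ], , drop = FALSE]
      p <- pts[out, , drop = FALSE]
      d2[, t] <- pmin(point_seg_dist2(p, v[1, ], v[2, ]),
                      point_seg_dist2(p, v[2, ], v[3, ]),
                      point_seg_dist2(p, v[3, ], v[1, ]))
    }
    hit[out] <- max.col(-d2, ties.method = "first")
  }
  hit
}

#' Map points through a fitted warp
#'
#' @param w a `stem_warp` (single-step or fold-back composition).
#' @param pts n x 2 matrix of in-plane points (mm).
#' @return n x 2 matrix of warped points.
#' @export
warp_points <- function(w, pts) {
  pts <- as.matrix(pts)
  if (ncol(pts) != 2L) stop("points must be n x 2")
  if (!is.null(w$steps)) {
    for (s in w$steps) pts <- warp_points(s, pts)
    return(pts)
  }
  tri <- locate_triangles(w, pts)
  out <- pts
  for (t in unique(tri)) {
    sel <- tri == t
    A <- w$affines[[t]]
    out[sel, ] <- t(A[, 1:2] %*% base::t(pts[sel, , drop = FALSE]) + A[, 3])
  }
  out
}

#' Per-triangle Jacobian determinants of a warp
#'
#' The determinant of each triangle's linear part; a negative value flags
#' local fold-over (the map reverses orientation there). For a fold-back
#' composition a list with one vector per partial step is returned.
#'
#' @param w a `stem_warp`.
#' @return numeric vector (single-step) or list of vectors (composed).
#' @export
jacobian_dets <- function(w) {
  if (!is.null(w$steps)) return(lapply(w$steps, jacobian_dets))
  vapply(w$affines, function(A) A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1],
         numeric(1))
}

#' Fit a landmark warp with fold-back control
#'
#' When the single-step piecewise-affine fit reverses orientation somewhere
#' (a negative per-triangle Jacobian determinant), the landmark displacement
#' is compartmentalized into `k` equal fractional steps: partial warps are
#' fitted between successive intermediate landmark configurations
#' (re-triangulated at each), and `k` is grown by doubling (2, 4, 8, ...)
#' up to `max_steps` until every partial warp has strictly positive
#' determinants. The composition still maps each atlas landmark onto its
#' MRI landmark (residual < 1e-6).
#'
#' @inheritParams fit_warp
#' @param max_steps largest admissible number of partial steps (default 16).
#' @return A `stem_warp`; when composed, `steps` holds the partial warps.
#' @export
fit_warp_foldback <- function(pairs, max_steps = 16L) {
  stopifnot(inherits(pairs, "stem_landmarks"), max_steps >= 1L)
  single <- fit_warp(pairs)
  if (all(jacobian_dets(single) > 0)) return(single)
  k <- 2L
  while (k <= max_steps) {
    steps <- vector("list", k)
    ok <- TRUE
    disp <- pairs$dst - pairs$src
    for (i in seq_len(k)) {
      a <- pairs$src + disp * (i - 1) / k
      b <- pairs$src + disp * i / k
      st <- tryCatch(fit_warp(landmark_pairs(a, b)), error = function(e) NULL)
      if (is.null(st) || any(jacobian_dets(st) <= 0)) { ok <- FALSE; break }
      steps[[i]] <- st
    }
    if (ok) {
      out <- structure(list(src = pairs$src, dst = pairs$dst,
                            triangles = single$triangles,
                            affines = single$affines, steps = steps),
                       class = "stem_warp")
      resid <- max(sqrt(rowSums((warp_points(out, pairs$src) - pairs$dst)^2)))
      if (resid < 1e-6) return(out)
    }
    k <- k * 2L
  }
  bad <- which(jacobian_dets(single) <= 0)
  stop("fold-back failure: no k <= ", max_steps,
       " removes negative Jacobians (offending triangle(s): ",
       paste(bad, collapse = ", "), ")")
}

#' Warp all contours of an atlas plate
#'
#' Maps every contour vertex (and the landmarks) through the warp; labels
#' and vertex counts are preserved, closure is implicit and so preserved.
#'
#' @param w a `stem_warp`.
#' @param plate a `stem_plate`.
#' @return A `stem_plate` with warped contours and landmarks.
#' @export
warp_contours <- function(w, plate) {
  stopifnot(inherits(plate, "stem_plate"))
  out <- plate
  out$contours <- lapply(plate$contours, function(cc) warp_points(w, cc))
  out$landmarks <- warp_points(w, plate$landmarks)
  out
}

#' Match atlas plates to coronal MRI slices
#'
#' The first and last plates are anchored to the given acquired slices; the
#' intermediate plates are placed by linear interpolation proportional to
#' their atlas anteroposterior spacing, and the subject volume is resampled
#' (trilinearly) at each interpolated position so there is exactly one MRI
#' slice per plate.
#'
#' @param plates list of `stem_plate`, strictly monotone in `position_mm`.
#' @param v coronal `stem_volume` (slice axis 2).
#' @param first_slice,last_slice 0-based acquired slice indices anchoring
#'   the first and last plate (`first_slice < last_slice`).
#' @return list with `correspondence` (data.frame: `plate_id`,
#'   `position_mm`, `slice_index`) and `slices` (list of [extract_slice()]
#'   results, one per plate).
#' @export
match_slices <- function(plates, v, first_slice, last_slice) {
  if (length(plates) < 2L) stop("need >= 2 plates")
  if (first_slice >= last_slice) stop("first_slice must precede last_slice")
  pos <- vapply(plates, function(p) p$position_mm, numeric(1))
  if (!(all(diff(pos) > 0) || all(diff(pos) < 0)))
    stop("ordering error: plate positions must be strictly monotone")
  rel <- (pos - pos[1]) / (pos[length(pos)] - pos[1])
  idx <- first_slice + rel * (last_slice - first_slice)
  slices <- lapply(idx, function(j) extract_slice(v, j))
  list(correspondence = data.frame(
         plate_id = vapply(plates, function(p) as.character(p$id),
                           character(1)),
         position_mm = pos, slice_index = idx),
       slices = slices)
}
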