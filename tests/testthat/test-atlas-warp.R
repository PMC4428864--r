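grid_landmarks <- function(n = 4, lim = 10) {
  as.matrix(expand.grid(seq(0, lim, length.out = n),
                        seq(0, lim, length.out = n)))
}

test_that("slice correspondence interpolates by relative atlas spacing", {
  mk <- function(pos) lapply(seq_along(pos), function(i)
    atlas_plate(paste0("p", i), pos[i], landmarks = grid_landmarks(2)))
  v <- as_volume(array(seq_len(16 * 30 * 16), c(16, 30, 16)),
                 diag(c(0.4, 0.4, 0.4, 1)))
  # two plates: pure anchoring, no interpolation
  ms2 <- match_slices(mk(c(0, 4)), v, 10, 20)
  expect_equal(ms2$correspondence$slice_index, c(10, 20))
  expect_length(ms2$slices, 2L)
  # three equally spaced plates: middle lands halfway
  ms3 <- match_slices(mk(c(0, 2, 4)), v, 10, 20)
  expect_equal(ms3$correspondence$slice_index[2], 15.0)
  # atlas spacings 1,1,2,1 anchored at 0 and 5 mm: proportional placement
  ms5 <- match_slices(mk(c(0, 1, 2, 4, 5)), v, 0, 25)
  expect_equal(ms5$correspondence$position_mm, c(0, 1, 2, 4, 5))
  expect_equal(ms5$correspondence$slice_index, c(0, 5, 10, 20, 25))
  # resampled slice at a fractional index interpolates between neighbours
  half <- extract_slice(v, 12.5)$image
  expect_close(half, (extract_slice(v, 12)$image +
                      extract_slice(v, 13)$image) / 2, 1e-9)
  expect_error(match_slices(mk(c(0, 3, 2)), v, 0, 10), "monotone")
  expect_error(match_slices(mk(c(0, 4)), v, 20, 10), "precede")
})

test_that("zero-displacement pairs give the identity warp", {
  lm <- grid_landmarks()
  w <- fit_warp(landmark_pairs(lm, lm))
  probe <- cbind(runif(40, -2, 12), runif(40, -2, 12))
  expect_close(warp_points(w, probe), probe, 1e-9)
  expect_close(jacobian_dets(w), rep(1, nrow(w$triangles)), 1e-12)
})

test_that("a global affine is reproduced everywhere, including Jacobians", {
  lm <- grid_landmarks()
  A <- matrix(c(1.2, 0.3, -0.1, 0.9), 2, 2)
  b <- c(2, -1)
  dst <- t(A %*% t(lm)) + rep(b, each = nrow(lm))
  w <- fit_warp(landmark_pairs(lm, dst))
  set.seed(2)
  probe <- cbind(runif(60, 0, 10), runif(60, 0, 10))
  expect_close(warp_points(w, probe),
               t(A %*% t(probe)) + rep(b, each = 60), 1e-9)
  expect_close(jacobian_dets(w), rep(det(A), nrow(w$triangles)), 1e-9)
  # uniform 2x scale: all determinants 4
  w2 <- fit_warp(landmark_pairs(lm, 2 * lm))
  expect_close(jacobian_dets(w2), rep(4, nrow(w2$triangles)), 1e-12)
})

test_that("displaced landmarks interpolate exactly; centroids follow barycentric oracle", {
  src <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  dst <- rbind(c(0, 0), c(10, 0), c(0, 10), c(12, 11))
  w <- fit_warp(landmark_pairs(src, dst))
  expect_close(warp_points(w, src), dst, 1e-9)
  for (t in seq_len(nrow(w$triangles))) {
    tri <- w$triangles[t, ]
    cen <- colMeans(src[tri, ])
    # oracle: barycentric weights of the centroid are (1/3, 1/3, 1/3)
    expect_close(warp_points(w, rbind(cen)), colMeans(dst[tri, ]), 1e-9)
  }
})

test_that("warp is continuous across shared triangle edges", {
  set.seed(4)
  src <- cbind(runif(12, 0, 10), runif(12, 0, 10))
  dst <- src + matrix(rnorm(24, sd = 0.8), ncol = 2)
  w <- fit_warp(landmark_pairs(src, dst))
  edge_img <- function(A, p) as.numeric(A[, 1:2] %*% p + A[, 3])
  tri <- w$triangles
  for (t1 in seq_len(nrow(tri) - 1)) for (t2 in (t1 + 1):nrow(tri)) {
    shared <- intersect(tri[t1, ], tri[t2, ])
    if (length(shared) != 2L) next
    for (lam in c(0.25, 0.5, 0.75)) {
      p <- lam * src[shared[1], ] + (1 - lam) * src[shared[2], ]
      expect_close(edge_img(w$affines[[t1]], p),
                   edge_img(w$affines[[t2]], p), 1e-9)
    }
  }
})

test_that("degenerate landmark configurations are rejected", {
  line <- cbind(1:4, 2 * (1:4))
  expect_error(fit_warp(landmark_pairs(line, line)), "rank error|collinear")
  dup <- rbind(c(0, 0), c(0, 0), c(1, 1), c(2, 0))
  expect_error(fit_warp(landmark_pairs(dup, dup)), "duplicate")
})

test_that("fold-back control removes negative Jacobians and fails loudly at k = 1", {
  fp <- fold_pairs()
  single <- fit_warp(fp)
  expect_true(any(jacobian_dets(single) < 0))
  composed <- fit_warp_foldback(fp, max_steps = 16)
  expect_false(is.null(composed$steps))
  expect_true(all(unlist(jacobian_dets(composed)) > 0))
  expect_close(warp_points(composed, fp$src), fp$dst, 1e-6)
  expect_error(fit_warp_foldback(fp, max_steps = 1), "fold-back failure")
})

test_that("fold-back is a no-op for non-folding configurations", {
  lm <- grid_landmarks()
  dst <- lm + 0.5
  w1 <- fit_warp(landmark_pairs(lm, dst))
  w2 <- fit_warp_foldback(landmark_pairs(lm, dst))
  expect_null(w2$steps)
  expect_identical(w1$affines, w2$affines)
})

test_that("contour warping preserves labels, counts and scales area", {
  lm <- grid_landmarks(4, 20)
  sq <- rbind(c(5, 5), c(12, 5), c(12, 12), c(5, 12))
  plate <- atlas_plate("p", 0, contours = list(ROI = sq), landmarks = lm)
  idw <- fit_warp(landmark_pairs(lm, lm))
  same <- warp_contours(idw, plate)
  expect_close(same$contours$ROI, sq, 1e-9)
  trw <- fit_warp(landmark_pairs(lm, lm + rep(c(3, -2), each = nrow(lm))))
  moved <- warp_contours(trw, plate)
  expect_close(moved$contours$ROI, sq + rep(c(3, -2), each = 4), 1e-9)
  scw <- fit_warp(landmark_pairs(lm, 2 * lm))
  big <- warp_contours(scw, plate)
  # shoelace oracle: area scales by det = 4
  shoelace <- function(p) {
    j <- c(2:nrow(p), 1)
    abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
  }
  expect_close(shoelace(big$contours$ROI), 4 * shoelace(sq), 1e-9)
  expect_named(big$contours, "ROI")
  expect_equal(nrow(big$contours$ROI), nrow(sq))
})

test_that("plates survive a JSON round trip", {
  p1 <- atlas_plate("a", -1.2,
                    contours = list(X = rbind(c(0, 0), c(1, 0), c(1, 1)),
                                    Y = rbind(c(3, 3), c(4, 3), c(4, 5))),
                    landmarks = grid_landmarks(2))
  p2 <- atlas_plate("b", 0.8, contours = list(X = rbind(c(0, 0), c(2, 0),
                                                        c(1, 2))),
                    landmarks = grid_landmarks(2) + 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_plates(list(p1, p2), path)
  back <- read_plates(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$id, "a")
  expect_close(back[[1]]$contours$Y, p1$contours$Y, 1e-12)
  expect_close(back[[2]]$landmarks, p2$landmarks, 1e-12)
  expect_equal(back[[2]]$position_mm, 0.8)
})
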