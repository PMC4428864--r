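shoelace_area <- function(p) {
  j <- c(2:nrow(p), 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

test_that("contour resampling preserves shape and enforces orientation", {
  sq <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  r4 <- resample_contour(sq, 4)
  # corner-equivalent points, perimeter preserved within 1%
  expect_equal(sort(round(rowSums(abs(r4)), 9)), rep(2, 4))
  per <- function(p) sum(sqrt(rowSums((p[c(2:nrow(p), 1), ] - p)^2)))
  expect_lt(abs(per(r4) - 8) / 8, 0.01)
  circ <- resample_contour(circle_contour(5, 100), 360)
  expect_lt(max(abs(sqrt(rowSums(circ^2)) - 5)), 5 * 1.5e-3)
  # clockwise input comes back counterclockwise (signed area > 0)
  cw <- sq[4:1, ]
  expect_lt(shoelace_area(cw), 0)
  expect_gt(shoelace_area(resample_contour(cw, 16)), 0)
  expect_error(resample_contour(rbind(c(0, 0), c(0, 0), c(0, 0)), 8),
               "perimeter|distinct")
})

test_that("lofted cylinder encloses the analytic volume within 2%", {
  circ <- circle_contour(5, 100)
  st <- contour_stack("cyl", c(0, 10), list(circ, circ))
  m <- loft(st, n = 256)
  expect_true(watertight_audit(m)$watertight)
  expect_lt(abs(mesh_volume(m) - pi * 25 * 10) / (pi * 250), 0.02)
})

test_that("lofted prism with square cross-section is exact at corners", {
  sq <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  st <- contour_stack("prism", c(0, 3), list(sq, sq))
  m <- loft(st, n = 8)                     # corners + edge midpoints
  expect_close(mesh_volume(m), 4 * 3, 1e-9)
})

test_that("stack validation rejects degenerate inputs", {
  circ <- circle_contour()
  expect_error(contour_stack("x", 0, list(circ)), ">= 2 slices")
  expect_error(contour_stack("x", c(0, 1, 1), list(circ, circ, circ)),
               "monotone|crossing")
})

test_that("lofts over varying stacks stay watertight and positively oriented", {
  set.seed(6)
  for (rep in 1:4) {
    ns <- sample(3:6, 1)
    pos <- cumsum(runif(ns, 0.5, 2))
    ctr <- lapply(seq_len(ns), function(i) {
      r <- runif(1, 2, 5)
      sweep(circle_contour(r, 60), 2, rnorm(2), "+")
    })
    m <- loft(contour_stack("r", pos, ctr), n = 64)
    expect_true(watertight_audit(m)$watertight)
    expect_gt(mesh_volume(m), 0)
  }
})

test_that("voxelization matches analytic volume and converges under refinement", {
  circ <- circle_contour(5, 100)
  m <- loft(contour_stack("cyl", c(0, 10), list(circ, circ)), n = 256)
  mkgrid <- function(h) {
    a <- diag(c(h, h, h, 1))
    a[1:3, 4] <- c(-6, -1, -6)
    as_volume(array(0, c(ceiling(12 / h), ceiling(12 / h),
                         ceiling(12 / h))), a)
  }
  # analytic: cylinder axis along y after lofting (x, position, z)
  v04 <- voxelize(m, mkgrid(0.4))
  expect_lt(abs(sum(v04$data) * 0.4^3 - pi * 250) / (pi * 250), 0.05)
  v02 <- voxelize(m, mkgrid(0.2))
  expect_lt(abs(sum(v02$data) / sum(v04$data) - 8) / 8, 0.05)
  # mesh entirely outside the grid gives an empty mask
  far <- as_volume(array(0, c(5, 5, 5)),
                   { a <- diag(4); a[1:3, 4] <- c(100, 100, 100); a })
  expect_false(any(voxelize(m, far)$data))
  # non-watertight input is rejected
  open_mesh <- as_mesh(m$vertices, m$faces[-1, ], "open")
  expect_error(voxelize(open_mesh, mkgrid(0.4)), "watertight")
})

test_that("overlap reports exact counts with Jaccard and asymmetric fractions", {
  d <- c(20, 20, 20)
  A <- array(FALSE, d); A[1:10, 1:10, 1:10] <- TRUE
  B <- array(FALSE, d); B[1:10, 1:10, 6:15] <- TRUE
  ma <- as_mask(A, diag(4), label = "a")
  mb <- as_mask(B, diag(4), label = "b")
  ov <- overlap(ma, mb)
  # exhaustive oracle: 10 x 10 x 5 shared slab of two 10^3 cubes
  expect_equal(ov$n_intersection, 500L)
  expect_equal(ov$n_union, 1500L)
  expect_close(ov$jaccard_pct, 100 * 500 / 1500, 1e-9)
  expect_close(ov$frac_of_a_pct, 50, 1e-9)
  # symmetry of the Jaccard number
  ov2 <- overlap(mb, ma)
  expect_equal(ov$jaccard_pct, ov2$jaccard_pct)
  expect_equal(overlap(ma, ma)$jaccard_pct, 100)
  disj <- as_mask(array(FALSE, d) | outer(outer(1:20 > 15, rep(TRUE, 20)),
                                          rep(TRUE, 20)), diag(4))
  expect_equal(overlap(ma, disj)$jaccard_pct, 0)
  empty <- as_mask(array(FALSE, d), diag(4))
  expect_error(overlap(empty, empty), "both masks empty")
  expect_error(overlap(ma, as_mask(array(FALSE, c(5, 5, 5)), diag(4))),
               "grid mismatch")
})

test_that("overlap decreases monotonically as one mask erodes away", {
  d <- c(20, 20, 20)
  A <- array(FALSE, d); A[5:15, 5:15, 5:15] <- TRUE
  ma <- as_mask(A, diag(4))
  prev <- 100
  for (k in 0:4) {
    B <- array(FALSE, d)
    B[(5 + k):15, 5:15, 5:15] <- TRUE
    j <- overlap(ma, as_mask(B, diag(4)))$jaccard_pct
    expect_lte(j, prev + 1e-12)
    prev <- j
  }
})

test_that("meshes export to PLY and OBJ", {
  circ <- circle_contour(2, 24)
  m <- loft(contour_stack("c", c(0, 1), list(circ, circ)), n = 24)
  ply <- withr::local_tempfile(fileext = ".ply")
  obj <- withr::local_tempfile(fileext = ".obj")
  write_mesh(m, ply); write_mesh(m, obj)
  hdr <- readLines(ply, n = 4)
  expect_equal(hdr[1], "ply")
  expect_match(hdr[3], as.character(nrow(m$vertices)))
  ol <- readLines(obj)
  expect_equal(sum(startsWith(ol, "v ")), nrow(m$vertices))
  expect_equal(sum(startsWith(ol, "f ")), nrow(m$faces))
})
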