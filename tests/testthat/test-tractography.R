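uniform_field <- function(d = c(9, 9, 9), dir = c(0, 0, 1), fa = 0.8,
                          kappa = 48) {
  nv <- prod(d)
  structure(list(dir = array(rep(dir, each = nv), c(d, 3)),
                 fa = array(fa, d), kappa = array(kappa, d),
                 evals = array(0, c(d, 3)), affine = diag(4), kappa0 = 60),
            class = "stem_field")
}

test_that("direction sampling honours concentration and axial symmetry", {
  f_hi <- uniform_field(kappa = 1e7)
  set.seed(1)
  mu <- c(0, 0, 1)
  d <- sample_direction(f_hi, matrix(rep(c(4, 4, 4), 100), ncol = 3,
                                     byrow = TRUE))
  # huge kappa: draw equals the axis up to sign
  expect_gt(min(abs(d[, 3])), 1 - 1e-5)
  # kappa = 0: uniform on the sphere (small mean resultant length)
  f_0 <- uniform_field(kappa = 0)
  set.seed(2)
  prev <- matrix(rep(mu, 1e4), ncol = 3, byrow = TRUE)
  u <- sample_direction(f_0, matrix(rep(c(4, 4, 4), 1e4), ncol = 3,
                                    byrow = TRUE))
  expect_lt(sqrt(sum(colMeans(u)^2)), 0.1)
  expect_close(rowSums(u^2), rep(1, 1e4), 1e-9)
  # prev = -mu with large kappa: the sign flip is honoured
  set.seed(3)
  d2 <- sample_direction(f_hi, matrix(rep(c(4, 4, 4), 50), ncol = 3,
                                      byrow = TRUE),
                         prev = matrix(rep(-mu, 50), ncol = 3, byrow = TRUE))
  expect_lt(max(d2[, 3]), -1 + 1e-5)
})

test_that("straight-tube tracking accepts nearly all streamlines on target", {
  fx <- fx_tube()
  res <- track(fx$field, fx$seed, list(fx$way), tracking_params(seed = 7))
  expect_gte(mean(res$streamlines$accepted), 0.95)
  # visitation support stays within 2 voxels of the tube
  vis <- which(res$visitation$counts > 0, arr.ind = TRUE) - 1L
  d2 <- (vis[, 1] - 12)^2 + (vis[, 3] - 12)^2
  expect_lte(max(sqrt(d2)), fx$tube$radius + 2)
  # visitation counts bounded by samples x seed voxels
  expect_lte(max(res$visitation$counts), res$visitation$total_samples)
  # acceptance soundness: every accepted streamline hits the waypoint
  for (i in which(res$streamlines$accepted)[1:25]) {
    p <- res$streamlines$paths[[i]]
    ijk <- round(p)                          # identity affine, 1 mm grid
    inb <- ijk[, 2] >= 0 & ijk[, 2] < 26
    expect_true(any(fx$way$data[ijk[inb, , drop = FALSE] + 1L]))
  }
})

test_that("streamline vertices are spaced exactly one step apart", {
  fx <- fx_tube()
  res <- track(fx$field, fx$seed, list(fx$way),
               tracking_params(seed = 5, samples = 5))
  for (p in res$streamlines$paths[1:20]) {
    if (nrow(p) < 2) next
    expect_close(sqrt(rowSums(diff(p)^2)), rep(0.5, nrow(p) - 1), 1e-6)
  }
})

test_that("tracking is bit-identical under a fixed seed", {
  fx <- fx_tube()
  a <- track(fx$field, fx$seed, list(fx$way),
             tracking_params(seed = 3, samples = 5))
  b <- track(fx$field, fx$seed, list(fx$way),
             tracking_params(seed = 3, samples = 5))
  expect_identical(a$visitation$counts, b$visitation$counts)
  expect_identical(a$streamlines$paths, b$streamlines$paths)
  c <- track(fx$field, fx$seed, list(fx$way),
             tracking_params(seed = 4, samples = 5))
  expect_false(identical(a$visitation$counts, c$visitation$counts))
})

test_that("an unreachable waypoint rejects every streamline", {
  fx <- fx_tube()
  off <- array(FALSE, dim(fx$field$fa))
  off[1:2, 1:2, 1:2] <- TRUE
  res <- track(fx$field, fx$seed, list(as_mask(off, fx$field$affine,
                                               role = "waypoint")),
               tracking_params(seed = 7, samples = 10))
  expect_equal(sum(res$streamlines$accepted), 0L)
  expect_true(all(res$visitation$counts == 0))
  expect_true(all(res$streamlines$reason == "missed waypoint"))
})

test_that("visitation thresholding behaves across the threshold range", {
  fx <- fx_tube()
  res <- track(fx$field, fx$seed, list(fx$way), tracking_params(seed = 7))
  vm <- res$visitation
  support <- threshold_map(vm, frac = 0)
  expect_equal(sum(support$data), sum(vm$counts > 0))
  expect_warning(empty <- threshold_map(vm, absolute = max(vm$counts) + 1),
                 "empty")
  expect_false(any(empty$data))
  tube_mask <- as_mask(fx$ph$masks$T$data, fx$field$affine, label = "truth")
  j <- overlap(threshold_map(vm, frac = 0.1), tube_mask)$jaccard_pct
  expect_gte(j, 50)
})

test_that("decussation waypoints confine visitation to the seeded bundle", {
  fx <- fx_decussation()
  seedA <- tube_section_mask(fx$tubes[[1]], j_slices = 2:3, role = "seed")
  cross <- tube_section_mask(fx$tubes[[1]], j_slices = 12:13, shrink = 1,
                             role = "waypoint")
  headA <- tube_section_mask(fx$tubes[[1]], j_slices = 21:22, shrink = 1,
                             role = "waypoint")
  res <- track(fx$field, seedA, list(cross, headA),
               tracking_params(seed = 11))
  A <- fx$ph$masks$SCP$data
  B <- fx$ph$masks$SCP_contra$data
  vm <- res$visitation$counts
  expect_gte(sum(vm[A]) / sum(vm), 0.90)
  expect_lte(sum(vm[B & !A]) / sum(vm), 0.10)
})

test_that("the full recipe loop transports masks across spaces and overlaps truth", {
  fx <- fx_decussation()
  xm <- diag(4); xm[1:3, 4] <- c(1.5, -2, 0.5)
  xfm <- as_xfm(xm, dof = 6)                 # DWI -> structural world
  sg <- as_volume(array(0, c(34L, 34L, 30L)), diag(c(0.8, 0.8, 0.8, 1)))
  ml <- fx$tubes[[3]]
  atlas <- resample_mask(fx$ph$masks$ML, xfm, sg)
  atlas$label <- "ML_atlas"
  seedS <- resample_mask(tube_section_mask(ml, j_slices = 2:3,
                                           role = "seed"), xfm, sg)
  seedS$role <- "seed"
  wayS <- resample_mask(tube_section_mask(ml, j_slices = 21:22, shrink = 1,
                                          role = "waypoint"), xfm, sg)
  rec <- list(seed = seedS, waypoints = list(wayS), atlas_mask = atlas,
              xfm = xfm)
  out <- run_tract_recipe(rec, fx$field, tracking_params(seed = 5),
                          structural_grid = sg)
  expect_gte(out$overlap$jaccard_pct, 40)
  expect_lt(out$overlap$jaccard_pct, 100)
  expect_error(run_tract_recipe(list(seed = seedS), fx$field),
               "transform")
})

test_that("an identity transform leaves the visitation map unchanged", {
  fx <- fx_tube()
  dwi_grid <- as_volume(array(0, dim(fx$field$fa)), fx$field$affine)
  rec <- list(seed = fx$seed, waypoints = list(fx$way),
              atlas_mask = as_mask(fx$ph$masks$T$data, fx$field$affine,
                                   label = "truth"),
              xfm = as_xfm(diag(4), dof = 6))
  out <- run_tract_recipe(rec, fx$field, tracking_params(seed = 7),
                          structural_grid = dwi_grid)
  direct <- track(fx$field, fx$seed, list(fx$way), tracking_params(seed = 7))
  expect_identical(out$visitation$counts, direct$visitation$counts)
  expect_identical(array(out$tract_mask$data, dim(fx$field$fa)),
                   threshold_map(direct$visitation, frac = 0.1)$data)
})

test_that("contradictory waypoints yield an empty tallied rejection set", {
  fx <- fx_tube()
  d <- dim(fx$field$fa)
  w1 <- array(FALSE, d); w1[1:2, 1:2, 1:2] <- TRUE
  w2 <- array(FALSE, d); w2[22:23, 24:25, 22:23] <- TRUE
  dwi_grid <- as_volume(array(0, d), fx$field$affine)
  rec <- list(seed = fx$seed,
              waypoints = list(as_mask(w1, fx$field$affine),
                               as_mask(w2, fx$field$affine)),
              atlas_mask = as_mask(fx$ph$masks$T$data, fx$field$affine),
              xfm = as_xfm(diag(4), dof = 6))
  expect_warning(out <- run_tract_recipe(rec, fx$field,
                                         tracking_params(seed = 7,
                                                         samples = 5),
                                         structural_grid = dwi_grid),
                 "empty")
  expect_false(any(out$tract_mask$data))
  expect_equal(unname(out$rejections["missed waypoint"]),
               length(out$streamlines$paths))
})

test_that("streamlines export to a readable TrackVis header", {
  fx <- fx_tube()
  res <- track(fx$field, fx$seed, list(fx$way),
               tracking_params(seed = 2, samples = 2))
  tf <- withr::local_tempfile(fileext = ".trk")
  write_trk(res$streamlines, tf, voxel_size = c(1, 1, 1),
            dim = dim(fx$field$fa))
  con <- file(tf, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  expect_equal(rawToChar(magic[1:5]), "TRACK")
  expect_equal(file.size(tf) > 1000, TRUE)
})
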