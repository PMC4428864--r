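# Shared fixtures, built once per test run (all generated in code).

.fx <- new.env(parent = emptyenv())

# single straight tube DWI phantom + tensor fit + end masks
fx_tube <- function() {
  if (is.null(.fx$tube)) {
    tube <- list(name = "T", radius = 3,
                 path = rbind(c(12, 2, 12), c(12, 23, 12)))
    ph <- make_dwi_phantom(list(tube), dims = c(24L, 26L, 24L),
                           snr = NULL, seed = 1)
    field <- fit_tensor_field(ph$volume)
    seed <- tube_section_mask(tube, dims = c(24L, 26L, 24L),
                              j_slices = 2:3, role = "seed")
    way <- tube_section_mask(tube, dims = c(24L, 26L, 24L),
                             j_slices = 21:22, shrink = 1,
                             role = "waypoint")
    .fx$tube <- list(tube = tube, ph = ph, field = field,
                     seed = seed, way = way)
  }
  .fx$tube
}

# crossing-bundle (decussation) phantom + tensor fit
fx_decussation <- function() {
  if (is.null(.fx$dec)) {
    tubes <- default_dwi_tubes()
    ph <- make_dwi_phantom(tubes, snr = NULL, seed = 1)
    .fx$dec <- list(tubes = tubes, ph = ph,
                    field = fit_tensor_field(ph$volume))
  }
  .fx$dec
}

# structural phantom (noiseless, age 10) with truth masks
fx_struct <- function() {
  if (is.null(.fx$struct))
    .fx$struct <- make_structural_phantom(structural_phantom_spec(age = 10))
  .fx$struct
}

# circle contour of radius r
circle_contour <- function(r = 5, n = 100) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th))
}

# quad configuration whose single-step warp folds but whose fractional
# steps re-triangulate cleanly (diagonal flip)
fold_pairs <- function() {
  landmark_pairs(rbind(c(0, 0), c(8, 0), c(4, 2), c(4, -20)),
                 rbind(c(0, 0), c(8, 0), c(4, -2), c(4, -20)))
}

expect_close <- function(x, y, tol = 1e-9) expect_lt(max(abs(x - y)), tol)
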