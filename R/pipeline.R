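#' Pipeline configuration validation
#'
#' Checks that every referenced input exists before any compute runs and
#' normalizes defaults (warp `max_steps`, loft ring size, tracking
#' parameters, threshold fraction, seed).
#'
#' @param cfg named list; see [run_warp_pipeline()] and
#'   [run_tract_pipeline()] for the fields each pipeline uses.
#' @return the normalized config.
#' @export
validate_config <- function(cfg) {
  for (f in c("volume", "field")) {
    if (is.character(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("validation error: missing input file '", cfg[[f]], "'")
  }
  cfg$max_steps <- cfg$max_steps %||% 16L
  cfg$loft_n <- cfg$loft_n %||% 96L
  cfg$threshold_frac <- cfg$threshold_frac %||% 0.1
  cfg$seed <- cfg$seed %||% 1L
  cfg$params <- cfg$params %||% tracking_params(seed = cfg$seed)
  cfg
}

md5_of <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(obj, tf)
  unname(tools::md5sum(tf))
}

write_provenance <- function(path, stage, params, seed, inputs = list()) {
  side <- paste0(path, ".prov.json")
  jsonlite::write_json(list(
    tool = "stemwarp", version = as.character(utils::packageVersion("stemwarp")),
    stage = stage, seed = seed, params = params,
    inputs = inputs, written = format(Sys.time(), tz = "UTC")),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(side)
}

#' Run the atlas-warping pipeline end to end
#'
#' crop -> slice correspondence -> per-plate fold-back warp fit -> contour
#' warping -> per-region lofting -> voxelization. Artifacts (warped plates
#' JSON, PLY meshes, NIfTI masks) are written under `cfg$out_dir` with a
#' JSON provenance sidecar each; any stage failure aborts with a
#' stage-tagged error.
#'
#' @param cfg list: `volume` (coronal `stem_volume` or NIfTI path),
#'   `plates` (list of `stem_plate` or JSON path), `pairs` (list of
#'   `stem_landmarks`, one per plate), `first_slice`, `last_slice`
#'   (0-based anchors), optional `crop` (`list(lo, hi)`), `max_steps`,
#'   `loft_n`, `out_dir`, `seed`.
#' @return list: `correspondence`, `warped` (plates), `meshes`, `masks`.
#' @export
run_warp_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  if (is.null(cfg$plates)) stop("validation error: no atlas plates supplied")
  if (is.null(cfg$pairs)) stop("validation error: no landmark pairs supplied")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  v <- stage("load", {
    if (is.character(cfg$volume)) read_volume(cfg$volume) else cfg$volume
  })
  plates <- stage("load", {
    if (is.character(cfg$plates)) read_plates(cfg$plates) else cfg$plates
  })
  if (length(cfg$pairs) != length(plates))
    stop("validation error: one landmark-pair set per plate required")
  if (!is.null(cfg$crop))
    v <- stage("crop", crop_box(v, cfg$crop$lo, cfg$crop$hi))
  ms <- stage("match_slices",
              match_slices(plates, v, cfg$first_slice, cfg$last_slice))
  warps <- stage("fit_warp", lapply(cfg$pairs, fit_warp_foldback,
                                    max_steps = cfg$max_steps))
  warped <- stage("warp_contours", Map(warp_contours, warps, plates))
  regions <- unique(unlist(lapply(warped, function(p) names(p$contours))))
  meshes <- stage("loft", {
    out <- list()
    for (rg in regions) {
      keep <- vapply(warped, function(p) rg %in% names(p$contours),
                     logical(1))
      if (sum(keep) < 2L) next
      pos <- vapply(warped[keep], function(p) p$position_mm, numeric(1))
      ctr <- lapply(warped[keep], function(p) p$contours[[rg]])
      out[[rg]] <- loft(contour_stack(rg, pos, ctr), n = cfg$loft_n)
    }
    out
  })
  masks <- stage("voxelize", lapply(meshes, voxelize, grid = v))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    pj <- file.path(cfg$out_dir, "warped_plates.json")
    write_plates(warped, pj)
    write_provenance(pj, "warp_contours",
                     list(max_steps = cfg$max_steps), cfg$seed,
                     list(volume = md5_of(v$data)))
    for (rg in names(meshes)) {
      mp <- file.path(cfg$out_dir, paste0("mesh_", rg, ".ply"))
      write_mesh(meshes[[rg]], mp)
      write_provenance(mp, "loft", list(n = cfg$loft_n), cfg$seed)
      kp <- file.path(cfg$out_dir, paste0("mask_", rg, ".nii.gz"))
      write_volume(masks[[rg]], kp)
      write_provenance(kp, "voxelize", list(), cfg$seed)
    }
  }
  list(correspondence = ms$correspondence, warped = warped,
       meshes = meshes, masks = masks)
}

#' Run the tractography pipeline over a set of recipes
#'
#' Executes each recipe with [run_tract_recipe()] and assembles the
#' overlap table (tract versus warped-atlas mask). An empty recipe list
#' yields an empty table with a warning.
#'
#' @param cfg list: `field` (`stem_field`) or `dwi` (4D `stem_volume` with
#'   gradients, tensor-fitted on the fly), `recipes` (named list; see
#'   [run_tract_recipe()]), `params` ([tracking_params()]), optional
#'   `structural_grid`, `out_dir`, `seed`.
#' @return list: `table` (data.frame of overlap rows), `results` (per
#'   recipe).
#' @export
run_tract_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  field <- cfg$field %||% (if (!is.null(cfg$dwi)) fit_tensor_field(cfg$dwi)
                           else stop("validation error: no field or dwi input"))
  if (is.null(cfg$recipes) || !length(cfg$recipes)) {
    warning("recipe list is empty", call. = FALSE)
    return(list(table = data.frame(label_a = character(),
                                   label_b = character(),
                                   n_intersection = integer(),
                                   n_union = integer(),
                                   jaccard_pct = numeric(),
                                   frac_of_a_pct = numeric(),
                                   frac_of_b_pct = numeric()),
                results = list()))
  }
  for (nm in names(cfg$recipes)) {
    rc <- cfg$recipes[[nm]]
    if (is.null(rc$seed) || is.null(rc$xfm))
      stop("validation error: recipe '", nm, "' is missing seed mask or transform")
  }
  results <- lapply(cfg$recipes, run_tract_recipe, field = field,
                    params = cfg$params,
                    structural_grid = cfg$structural_grid)
  rows <- lapply(names(results), function(nm) {
    o <- results[[nm]]$overlap
    if (is.null(o)) return(NULL)
    data.frame(label_a = nm, label_b = o$label_b,
               n_intersection = o$n_intersection, n_union = o$n_union,
               jaccard_pct = o$jaccard_pct,
               frac_of_a_pct = o$frac_of_a_pct,
               frac_of_b_pct = o$frac_of_b_pct)
  })
  tab <- do.call(rbind, rows) %||% data.frame()
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    cp <- file.path(cfg$out_dir, "overlap.csv")
    utils::write.csv(tab, cp, row.names = FALSE)
    write_provenance(cp, "overlap", list(params = unclass(cfg$params)),
                     cfg$seed)
    for (nm in names(results)) {
      tp <- file.path(cfg$out_dir, paste0("tract_", nm, ".nii.gz"))
      write_volume(results[[nm]]$tract_mask, tp)
      write_provenance(tp, "threshold_map",
                       list(threshold = attr(results[[nm]]$tract_mask,
                                             "threshold")), cfg$seed)
    }
  }
  list(table = tab, results = results)
}
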