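#' Structured run configuration
#'
#' A single YAML (or list) configuration binds the pipeline stages together:
#' input paths, per-stage parameters, the RNG seed and the segmentation
#' backend. Flag-style overrides passed as `...` win over file values.
#'
#' Recognised keys (all optional unless a stage needs them): `out` (output
#' directory), `seed`, `backend` (`"obia"` or `"color-threshold"`), paths
#' `image`, `gcps`, `zones`, `legend`, `training`, `overrides`, `reported`;
#' parameters `scale`, `band_weights`, `connectivity`, `tolerance`,
#' `black_max_channel`, `black_max_px`, `max_absorption_passes`, `margin`,
#' `min_coverage`, `target_total`, `free_class`, `n_trees`, `gcp_order`;
#' and a `simulate:` block with [synthetic_map_spec()] fields.
#'
#' @param config path to a YAML file, or a named list.
#' @param ... overrides (e.g. `seed = 7`, `backend = "obia"`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(config = NULL, ...) {
  cfg <- list()
  if (is.character(config)) cfg <- yaml::read_yaml(config)
  else if (is.list(config)) cfg <- config
  dots <- list(...)
  cfg[names(dots)] <- dots
  defaults <- list(out = "mapreclaim_out", backend = "obia", scale = 10,
                   band_weights = c(1, 1, 1), connectivity = 4L,
                   tolerance = 30, black_max_channel = 60, black_max_px = 5L,
                   max_absorption_passes = 100L, margin = 25,
                   min_coverage = 0.25, target_total = 30e6, free_class = 1L,
                   n_trees = 500L, gcp_order = 3L, training_fraction = 0.1)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$seed)) stop("the configuration must set a seed")
  if (!cfg$backend %in% c("obia", "color-threshold"))
    stop("backend must be 'obia' or 'color-threshold'")
  structure(cfg, class = "run_config")
}

art <- function(cfg, ...) file.path(cfg$out, ...)

need_artifact <- function(cfg, file, producer) {
  p <- art(cfg, file)
  if (!file.exists(p))
    stop(sprintf("missing artifact '%s'; run stage '%s' first", file,
                 producer), call. = FALSE)
  p
}

write_manifest <- function(cfg, stage, inputs, params, elapsed) {
  m <- list(stage = stage, inputs = inputs, parameters = params,
            seed = cfg$seed, backend = cfg$backend,
            software = paste0("mapreclaim ",
                              as.character(utils::packageVersion("mapreclaim"))),
            wall_time_s = round(elapsed, 3))
  jsonlite::write_json(m, art(cfg, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

stage_guard <- function(cfg, stage, outputs, overwrite) {
  hit <- outputs[file.exists(file.path(cfg$out, outputs))]
  if (length(hit) && !overwrite)
    stop(sprintf("stage '%s' outputs exist (%s); re-run with overwrite = TRUE",
                 stage, paste(hit, collapse = ", ")), call. = FALSE)
}

load_run_legend <- function(cfg) {
  if (!is.null(cfg$legend) && file.exists(cfg$legend)) read_legend(cfg$legend)
  else if (file.exists(art(cfg, "legend.csv"))) read_legend(art(cfg, "legend.csv"))
  else deer_density_legend()
}

#' Run one pipeline stage
#'
#' Stages mirror the digitization sequence — georeference, build image
#' objects, classify, correct, summarize — plus `simulate` for synthetic
#' inputs and `all` for the full chain. Every stage writes its artifacts
#' under `cfg$out` together with a JSON manifest (inputs, parameters, seed,
#' software version, wall time), and refuses to clobber existing outputs
#' unless `overwrite = TRUE`. A stage whose upstream artifact is missing
#' stops with a message naming the stage to run first.
#'
#' @param name one of `"simulate"`, `"georef"`, `"segment"`, `"train"`,
#'   `"classify"`, `"cleanup"`, `"zonal"`, `"demography"`, `"compare"`,
#'   `"all"`.
#' @param cfg a [run_config].
#' @param overwrite allow overwriting existing stage outputs.
#' @return Invisibly, the paths of the artifacts written.
#' @export
run_stage <- function(name, cfg, overwrite = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  stages <- c("simulate", "georef", "segment", "train", "classify",
              "cleanup", "zonal", "demography", "compare", "all")
  name <- match.arg(name, stages)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  if (name == "all") {
    chain <- c(if (is.null(cfg$image)) "simulate",
               if (!is.null(cfg$gcps)) "georef",
               if (cfg$backend == "obia") c("segment", "train"),
               "classify", "cleanup", "zonal", "demography",
               if (!is.null(cfg$reported)) "compare")
    out <- unlist(lapply(chain, run_stage, cfg = cfg, overwrite = overwrite))
    return(invisible(out))
  }
  t0 <- proc.time()[["elapsed"]]
  written <- switch(name,
    simulate = stage_simulate(cfg, overwrite),
    georef = stage_georef(cfg, overwrite),
    segment = stage_segment(cfg, overwrite),
    train = stage_train(cfg, overwrite),
    classify = stage_classify(cfg, overwrite),
    cleanup = stage_cleanup(cfg, overwrite),
    zonal = stage_zonal(cfg, overwrite),
    demography = stage_demography(cfg, overwrite),
    compare = stage_compare(cfg, overwrite))
  write_manifest(cfg, name, written$inputs, written$params,
                 proc.time()[["elapsed"]] - t0)
  invisible(written$outputs)
}

stage_simulate <- function(cfg, overwrite) {
  outs <- c("image.png", "clean.png", "zones.geojson", "truth_classes.tsv",
            "truth_units.csv", "legend.csv")
  stage_guard(cfg, "simulate", outs, overwrite)
  sim_args <- if (is.null(cfg$simulate)) list() else cfg$simulate
  sim_args$seed <- cfg$seed
  spec <- do.call(synthetic_map_spec, sim_args)
  sim <- simulate_map(spec)
  write_raster(sim$image, art(cfg, "image.png"))
  write_raster(sim$clean, art(cfg, "clean.png"))
  write_vector(sim$zones, art(cfg, "zones.geojson"))
  write_int_raster(sim$truth$classes, art(cfg, "truth_classes.tsv"),
                   sim$truth$geotransform)
  write_int_raster(sim$truth$units, art(cfg, "truth_units.tsv"))
  utils::write.csv(sim$truth$unit_class, art(cfg, "truth_units.csv"),
                   row.names = FALSE)
  write_legend(spec$legend, art(cfg, "legend.csv"))
  list(outputs = file.path(cfg$out, outs), inputs = list(),
       params = spec[setdiff(names(spec), "legend")])
}

stage_georef <- function(cfg, overwrite) {
  stage_guard(cfg, "georef", "georef.png", overwrite)
  if (is.null(cfg$image) || is.null(cfg$gcps))
    stop("georef needs 'image' and 'gcps' paths in the configuration")
  img <- suppressWarnings(read_raster(cfg$image))
  gcps <- read_gcps(cfg$gcps)
  tr <- fit_polynomial_transform(gcps, order = cfg$gcp_order)
  out <- warp_image(img, tr)
  write_raster(out, art(cfg, "georef.png"))
  jsonlite::write_json(tr[c("order", "coeffs_x", "coeffs_y", "rms_residual")],
                       art(cfg, "transform.json"), auto_unbox = TRUE,
                       digits = NA)
  list(outputs = art(cfg, c("georef.png", "transform.json")),
       inputs = list(image = cfg$image, gcps = cfg$gcps),
       params = list(gcp_order = cfg$gcp_order,
                     rms_residual = tr$rms_residual))
}

run_input_image <- function(cfg) {
  if (file.exists(art(cfg, "georef.png"))) art(cfg, "georef.png")
  else if (!is.null(cfg$image) && file.exists(cfg$image)) cfg$image
  else need_artifact(cfg, "image.png", "simulate")
}

stage_segment <- function(cfg, overwrite) {
  outs <- c("labels.tsv", "objects.csv", "adjacency.csv")
  stage_guard(cfg, "segment", outs, overwrite)
  if (cfg$backend != "obia")
    stop("the segment stage applies to the 'obia' backend only")
  img <- read_raster(run_input_image(cfg))
  seg <- multiresolution_segment(img, segmentation_params(
    scale = cfg$scale, band_weights = cfg$band_weights,
    connectivity = cfg$connectivity))
  write_int_raster(seg$labels, art(cfg, "labels.tsv"), img$geotransform)
  utils::write.csv(seg$objects, art(cfg, "objects.csv"), row.names = FALSE)
  utils::write.csv(seg$adjacency, art(cfg, "adjacency.csv"), row.names = FALSE)
  list(outputs = art(cfg, outs),
       inputs = list(image = run_input_image(cfg)),
       params = list(scale = cfg$scale, connectivity = cfg$connectivity,
                     n_objects = nrow(seg$objects)))
}

load_segment_artifacts <- function(cfg) {
  lab <- read_int_raster(need_artifact(cfg, "labels.tsv", "segment"))
  gt <- attr(lab, "geotransform")
  attr(lab, "geotransform") <- NULL
  objects <- utils::read.csv(need_artifact(cfg, "objects.csv", "segment"))
  adjacency <- utils::read.csv(need_artifact(cfg, "adjacency.csv", "segment"))
  structure(list(labels = lab, objects = objects, adjacency = adjacency,
                 geotransform = gt, crs = "EPSG:5070",
                 params = segmentation_params(scale = cfg$scale)),
            class = "segment_map")
}

stage_train <- function(cfg, overwrite) {
  stage_guard(cfg, "train", c("model.rds", "model.json"), overwrite)
  seg <- load_segment_artifacts(cfg)
  has_training <- !is.null(cfg[["training"]]) && file.exists(cfg[["training"]])
  training <- if (has_training) {
    utils::read.csv(cfg[["training"]])
  } else if (file.exists(art(cfg, "training.csv"))) {
    utils::read.csv(art(cfg, "training.csv"))
  } else {
    # synthetic runs: emulate the manual labelling of a sample of objects
    truth <- read_int_raster(need_artifact(cfg, "truth_classes.tsv",
                                           "simulate"))
    lg <- load_run_legend(cfg)
    tr <- sample_training_objects(seg, truth, lg,
                                  fraction = cfg$training_fraction,
                                  black_max_channel = cfg$black_max_channel,
                                  seed = cfg$seed + 3L)
    utils::write.csv(tr, art(cfg, "training.csv"), row.names = FALSE)
    tr
  }
  model <- train_classifier(seg$objects, training, n_trees = cfg$n_trees,
                            seed = cfg$seed + 4L)
  saveRDS(model, art(cfg, "model.rds"))
  jsonlite::write_json(list(seed = model$seed, features = model$features,
                            classes = model$classes,
                            oob_accuracy = model$oob_accuracy),
                       art(cfg, "model.json"), auto_unbox = TRUE, digits = NA)
  list(outputs = art(cfg, c("model.rds", "model.json", "training.csv")),
       inputs = list(training = cfg[["training"]]),
       params = list(n_trees = cfg$n_trees,
                     oob_accuracy = model$oob_accuracy))
}

stage_classify <- function(cfg, overwrite) {
  outs <- c("classes.tsv", "object_classes.csv")
  stage_guard(cfg, "classify", outs, overwrite)
  lg <- load_run_legend(cfg)
  if (cfg$backend == "obia") {
    seg <- load_segment_artifacts(cfg)
    model <- readRDS(need_artifact(cfg, "model.rds", "train"))
    cmap <- predict_classes(model, seg$objects, seg, lg)
    utils::write.csv(cmap$objects, art(cfg, "object_classes.csv"),
                     row.names = FALSE)
  } else {
    img <- read_raster(run_input_image(cfg))
    cmap <- color_threshold_segment(img, lg, tolerance = cfg$tolerance)
    utils::write.csv(data.frame(id = integer(), class_id = integer(),
                                provenance = character()),
                     art(cfg, "object_classes.csv"), row.names = FALSE)
  }
  write_int_raster(cmap$class_id, art(cfg, "classes.tsv"), cmap$geotransform)
  list(outputs = art(cfg, outs), inputs = list(image = run_input_image(cfg)),
       params = list(backend = cfg$backend))
}

load_classified_map <- function(cfg, file, producer) {
  cm <- read_int_raster(need_artifact(cfg, file, producer))
  gt <- attr(cm, "geotransform")
  attr(cm, "geotransform") <- NULL
  lg <- load_run_legend(cfg)
  objects <- NULL; labels <- NULL
  if (file.exists(art(cfg, "object_classes.csv"))) {
    objects <- utils::read.csv(art(cfg, "object_classes.csv"))
    if (!nrow(objects)) objects <- NULL
  }
  if (!is.null(objects) && file.exists(art(cfg, "labels.tsv"))) {
    labels <- read_int_raster(art(cfg, "labels.tsv"))
    attr(labels, "geotransform") <- NULL
  }
  classified_map(cm, lg, geotransform = gt, objects = objects,
                 labels = labels)
}

stage_cleanup <- function(cfg, overwrite) {
  stage_guard(cfg, "cleanup", "classes_clean.tsv", overwrite)
  cmap <- load_classified_map(cfg, "classes.tsv", "classify")
  seg <- if (cfg$backend == "obia") load_segment_artifacts(cfg) else NULL
  cmap <- absorb_black_objects(cmap, seg, cleanup_params(
    black_max_channel = cfg$black_max_channel,
    small_object_max_px = cfg$black_max_px,
    max_absorption_passes = cfg$max_absorption_passes))
  if (!is.null(cfg$overrides) && file.exists(cfg$overrides))
    cmap <- apply_overrides(cmap, utils::read.csv(cfg$overrides))
  write_int_raster(cmap$class_id, art(cfg, "classes_clean.tsv"),
                   cmap$geotransform)
  list(outputs = art(cfg, "classes_clean.tsv"),
       inputs = list(overrides = cfg$overrides),
       params = list(black_max_px = cfg$black_max_px))
}

run_zones <- function(cfg) {
  if (!is.null(cfg$zones) && file.exists(cfg$zones)) read_zones(cfg$zones)
  else read_zones(need_artifact(cfg, "zones.geojson", "simulate"))
}

stage_zonal <- function(cfg, overwrite) {
  outs <- c("zonal.csv", "state_areas.csv")
  stage_guard(cfg, "zonal", outs, overwrite)
  file <- if (file.exists(art(cfg, "classes_clean.tsv"))) "classes_clean.tsv"
          else "classes.tsv"
  cmap <- load_classified_map(cfg, file, "classify")
  zt <- zonal_class_areas(cmap, run_zones(cfg))
  zt <- assign_majority(zt, zonal_params(majority_margin = cfg$margin,
                                         min_coverage = cfg$min_coverage))
  write_zonal_table(zt, art(cfg, "zonal.csv"))
  utils::write.csv(zt$state_areas, art(cfg, "state_areas.csv"),
                   row.names = FALSE)
  saveRDS(zt, art(cfg, "zonal.rds"))
  list(outputs = art(cfg, outs), inputs = list(zones = cfg$zones),
       params = list(margin = cfg$margin, min_coverage = cfg$min_coverage))
}

stage_demography <- function(cfg, overwrite) {
  outs <- c("state_summary.csv", "calibration.json")
  stage_guard(cfg, "demography", outs, overwrite)
  if (!file.exists(art(cfg, "zonal.rds")))
    stop("missing artifact 'zonal.rds'; run stage 'zonal' first", call. = FALSE)
  zt <- readRDS(art(cfg, "zonal.rds"))
  lg <- zt$legend
  spec <- calibration_spec(target_total = cfg$target_total,
                           free_class = cfg$free_class)
  v <- tryCatch(calibrate_free_class(zt, spec), error = function(e) NA_real_)
  if (!is.na(v))
    lg$classes$density[lg$classes$class_id == spec$free_class] <- v
  summary <- estimate_population(zt, lg, level = "state")
  utils::write.csv(summary, art(cfg, "state_summary.csv"), row.names = FALSE)
  jsonlite::write_json(list(free_class = spec$free_class,
                            calibrated_value = v,
                            target_total = spec$target_total),
                       art(cfg, "calibration.json"), auto_unbox = TRUE,
                       digits = NA)
  list(outputs = art(cfg, outs), inputs = list(),
       params = list(target_total = cfg$target_total,
                     calibrated_value = v))
}

stage_compare <- function(cfg, overwrite) {
  stage_guard(cfg, "compare", "comparison.csv", overwrite)
  if (is.null(cfg$reported) || !file.exists(cfg$reported))
    stop("compare needs a 'reported' CSV (state,estimate)")
  summary <- utils::read.csv(need_artifact(cfg, "state_summary.csv",
                                           "demography"))
  reported <- utils::read.csv(cfg$reported)
  comp <- compare_estimates(reported,
                            data.frame(state = summary$state_id,
                                       estimate = summary$population))
  utils::write.csv(comp, art(cfg, "comparison.csv"), row.names = FALSE)
  list(outputs = art(cfg, "comparison.csv"),
       inputs = list(reported = cfg$reported),
       params = list(mae = attr(comp, "mae")))
}

#' Emulated manual labelling of a training sample
#'
#' Draws a random fraction of image objects and labels each the way an
#' analyst would: objects that look black (all band means at or below the
#' ink threshold) get the legend's black class, everything else the majority
#' ground-truth class under the object.
#'
#' @param seg a [segment_map][multiresolution_segment()].
#' @param truth truth class matrix (same grid).
#' @param legend a [map_legend].
#' @param fraction fraction of objects to label.
#' @param black_max_channel ink threshold (8-bit).
#' @param seed RNG seed.
#' @return data.frame `object_id`, `class_id`.
#' @export
sample_training_objects <- function(seg, truth, legend, fraction = 0.1,
                                    black_max_channel = 60, seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  ids <- seg$objects$id
  take <- sort(sample(ids, max(1L, round(fraction * length(ids)))))
  black <- black_class(legend)
  is_black <- detect_black_objects(seg$objects,
                                   cleanup_params(black_max_channel))
  lab <- vapply(take, function(id) {
    if (!is.na(black) && id %in% is_black) return(black)
    cls <- truth[seg$labels == id]
    as.integer(names(which.max(table(cls))))
  }, integer(1))
  data.frame(object_id = take, class_id = lab)
}
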