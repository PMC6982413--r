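#' Map legend: density classes, display colours, density values
#'
#' The legend drives everything downstream: display colours anchor the
#' colour-threshold backend and the synthetic renderer, density values
#' (animals/km^2) convert class areas to populations, and the special rows —
#' exactly one *nodata* class and optionally one *black* (cartographic ink)
#' class — mark pixels that carry no thematic value. `presence = FALSE`
#' classes (nodata, black, explicit absence classes) must have density 0.
#'
#' @param classes data.frame with columns `class_id` (unique integers),
#'   `name`, `red`, `green`, `blue` (0-255 display colour), `density`
#'   (animals/km^2, `>= 0`), `presence` (logical) and `role` (one of
#'   `"density"`, `"nodata"`, `"black"`).
#' @return An object of class `map_legend`.
#' @export
map_legend <- function(classes) {
  req <- c("class_id", "name", "red", "green", "blue", "density",
           "presence", "role")
  stopifnot(is.data.frame(classes), all(req %in% names(classes)))
  classes <- classes[req]
  classes$class_id <- as.integer(classes$class_id)
  if (anyDuplicated(classes$class_id)) stop("class ids must be unique")
  if (sum(classes$role == "nodata") != 1L)
    stop("legend must contain exactly one nodata class")
  if (sum(classes$role == "black") > 1L)
    stop("legend may contain at most one black (ink) class")
  # NA density marks a not-yet-calibrated density class
  if (any(classes$density < 0, na.rm = TRUE))
    stop("density values must be >= 0")
  if (any(!classes$presence & (is.na(classes$density) | classes$density != 0)))
    stop("presence = FALSE classes must have density 0")
  structure(list(classes = classes), class = "map_legend")
}

#' @export
print.map_legend <- function(x, ...) {
  cat(sprintf("<map_legend> %d classes (%d density)\n",
              nrow(x$classes), sum(x$classes$role == "density")))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' @rdname map_legend
#' @param legend a `map_legend`.
#' @return Helper accessors return class-id vectors / scalars.
#' @export
density_classes <- function(legend) {
  legend$classes$class_id[legend$classes$role == "density"]
}

#' @rdname map_legend
#' @export
nodata_class <- function(legend) {
  legend$classes$class_id[legend$classes$role == "nodata"]
}

#' @rdname map_legend
#' @export
black_class <- function(legend) {
  id <- legend$classes$class_id[legend$classes$role == "black"]
  if (length(id)) id else NA_integer_
}

#' White-tailed deer density legend
#'
#' The four-class deer density legend used throughout the worked examples:
#' class breaks <5.8, 5.8-11.6, 11.6-17.4 and >17.4 deer/km^2, valued at the
#' lower class bounds (5.8, 11.6, 17.4) with the open low class carrying a
#' calibratable value (default 1.85 deer/km^2, the value that reproduces a
#' 30-million-deer national total), plus white nodata and black ink classes.
#' Display colours are a well-separated yellow-to-dark-red ramp (pairwise
#' max-band distance >= 65).
#'
#' @param low_density density value for the open low class, deer/km^2.
#' @return A [map_legend].
#' @export
deer_density_legend <- function(low_density = 1.85) {
  map_legend(data.frame(
    class_id = c(0L, 1L, 2L, 3L, 4L, 9L),
    name = c("no data", "low (<5.8)", "5.8-11.6", "11.6-17.4", "high (>17.4)",
             "ink"),
    red   = c(255, 255, 230, 204, 103, 0),
    green = c(255, 255, 152,  37,   0, 0),
    blue  = c(255, 190,   0,  41,  13, 0),
    density = c(0, low_density, 5.8, 11.6, 17.4, 0),
    presence = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
    role = c("nodata", "density", "density", "density", "density", "black")))
}

#' Read/write a legend as CSV
#' @param path CSV with the columns of [map_legend()].
#' @return `read_legend`: a [map_legend].
#' @export
read_legend <- function(path) {
  map_legend(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_legend
#' @param legend a [map_legend] to write.
#' @export
write_legend <- function(legend, path) {
  utils::write.csv(legend$classes, path, row.names = FALSE)
  invisible(path)
}

## ---- classified map --------------------------------------------------------

#' Classified map container
#'
#' Per-pixel class ids on a georeferenced grid, with per-object classes and a
#' provenance tag for each pixel recording how its class was decided:
#' `model` (classifier), `rule` (rule-based cleanup), `override` (manual) or
#' `fallback-map` (filled from another map).
#'
#' @param class_id integer matrix of legend class ids (the nodata class id
#'   marks pixels without thematic value).
#' @param legend a [map_legend].
#' @param geotransform,crs georeferencing of the grid.
#' @param objects optional per-object table (`id`, `class_id`, `provenance`).
#' @param labels optional segment-label matrix matching `objects`.
#' @param provenance a single tag for all pixels or an integer matrix of
#'   codes (1 model, 2 rule, 3 override, 4 fallback-map).
#' @return An object of class `classified_map`.
#' @export
classified_map <- function(class_id, legend, geotransform = c(0, 1, 0, 0, 0, 1),
                           crs = "EPSG:5070", objects = NULL, labels = NULL,
                           provenance = "model") {
  stopifnot(is.matrix(class_id), inherits(legend, "map_legend"))
  known <- legend$classes$class_id
  if (!all(class_id %in% known))
    stop("class_id matrix contains ids absent from the legend")
  if (is.character(provenance)) {
    code <- provenance_code(provenance)
    provenance <- matrix(code, nrow(class_id), ncol(class_id))
  }
  stopifnot(all(dim(provenance) == dim(class_id)))
  storage.mode(class_id) <- "integer"
  storage.mode(provenance) <- "integer"
  structure(list(class_id = class_id, legend = legend,
                 geotransform = as.numeric(geotransform), crs = crs,
                 objects = objects, labels = labels, provenance = provenance),
            class = "classified_map")
}

provenance_code <- function(tag) {
  code <- match(tag, c("model", "rule", "override", "fallback-map"))
  if (anyNA(code)) stop("unknown provenance tag: ", tag)
  code
}

#' @export
print.classified_map <- function(x, ...) {
  tab <- table(factor(x$class_id, levels = x$legend$classes$class_id,
                      labels = x$legend$classes$name))
  cat(sprintf("<classified_map> %d x %d px\n", ncol(x$class_id), nrow(x$class_id)))
  print(tab)
  invisible(x)
}

## ---- random forest on image objects ---------------------------------------

#' Train a random-forest classifier on labelled image objects
#'
#' Features are the six per-object colour statistics (`mean_R`, `mean_G`,
#' `mean_B`, `sd_R`, `sd_G`, `sd_B`); the forest relates them to manually
#' assigned legend classes. Defaults: 500 trees, `floor(sqrt(6))` candidate
#' features per split, unlimited depth. The seed is mandatory so the fitted
#' forest — and every downstream map — is exactly reproducible.
#'
#' @param objects per-object table from [compute_object_stats()].
#' @param training data.frame `object_id`, `class_id` (the training sample).
#' @param classes class ids the model must be able to predict; defaults to
#'   the classes present in `training`. Any requested class with zero
#'   training objects is an error naming the class.
#' @param n_trees number of trees.
#' @param seed integer RNG seed (required).
#' @return An object of class `object_classifier` with the fitted forest,
#'   feature schema, class levels, seed and out-of-bag accuracy.
#' @export
train_classifier <- function(objects, training, classes = NULL,
                             n_trees = 500L, seed) {
  if (missing(seed)) stop("a seed is required for reproducible training")
  feats <- c("mean_R", "mean_G", "mean_B", "sd_R", "sd_G", "sd_B")
  stopifnot(all(feats %in% names(objects)),
            all(c("object_id", "class_id") %in% names(training)),
            nrow(training) > 0)
  if (!all(training$object_id %in% objects$id))
    stop("training object ids absent from the object table: ",
         paste(setdiff(training$object_id, objects$id), collapse = ", "))
  if (is.null(classes)) classes <- sort(unique(training$class_id))
  missing_cls <- setdiff(classes, training$class_id)
  if (length(missing_cls))
    stop("no training objects for class(es): ",
         paste(missing_cls, collapse = ", "))
  idx <- match(training$object_id, objects$id)
  x <- objects[idx, feats]
  y <- factor(training$class_id, levels = sort(as.integer(classes)))
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                   mtry = max(1L, floor(sqrt(length(feats)))))
  oob <- sum(diag(rf$confusion[, levels(y), drop = FALSE])) / length(y)
  structure(list(forest = rf, features = feats,
                 classes = as.integer(levels(y)), seed = seed,
                 oob_accuracy = oob),
            class = "object_classifier")
}

#' @export
print.object_classifier <- function(x, ...) {
  cat(sprintf("<object_classifier> %d classes, %d trees, OOB accuracy %.3f\n",
              length(x$classes), x$forest$ntree, x$oob_accuracy))
  invisible(x)
}

#' Assign a legend class to every image object
#'
#' Each object receives its forest majority-vote class; the pixel layer is
#' derived by looking object classes up through the segment labels, so pixel
#' and object classes agree by construction. Per-object vote fractions are
#' attached for optional manual review (no probability thresholding is
#' applied).
#'
#' @param model an [object_classifier][train_classifier].
#' @param objects per-object table (same feature schema as training).
#' @param seg a [segment_map][multiresolution_segment()] providing labels.
#' @param legend a [map_legend].
#' @return A [classified_map] with provenance `model`; nodata label pixels
#'   (label 0) get the legend's nodata class.
#' @export
predict_classes <- function(model, objects, seg, legend) {
  stopifnot(inherits(model, "object_classifier"))
  if (!all(model$features %in% names(objects)))
    stop("object table does not carry the model's feature schema: ",
         paste(setdiff(model$features, names(objects)), collapse = ", "))
  if (nrow(objects) == 0L) {
    empty <- matrix(nodata_class(legend), 0, 0)
    return(classified_map(empty, legend, seg$geotransform, seg$crs,
                          objects = data.frame(id = integer(),
                                               class_id = integer(),
                                               provenance = character())))
  }
  votes <- stats::predict(model$forest, objects[model$features], type = "vote",
                          norm.votes = TRUE)
  pick <- max.col(votes, ties.method = "first")
  cls <- as.integer(colnames(votes))[pick]
  obj <- data.frame(id = objects$id, class_id = cls, provenance = "model",
                    stringsAsFactors = FALSE)
  vote_max <- votes[cbind(seq_len(nrow(votes)), pick)]
  obj$vote_fraction <- vote_max
  lut <- integer(max(objects$id))
  lut[objects$id] <- cls
  cm <- seg$labels
  px <- matrix(nodata_class(legend), nrow(cm), ncol(cm))
  px[cm > 0L] <- lut[cm[cm > 0L]]
  classified_map(px, legend, seg$geotransform, seg$crs, objects = obj,
                 labels = seg$labels, provenance = "model")
}
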