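#' Calibration of the open density class
#'
#' Choropleth density classes are intervals; converting areas to populations
#' needs one value per class. The bounded classes take their lower bounds,
#' but the open low class has no natural value — it is solved so that the
#' map reproduces a known (independently estimated) total population `T`:
#' \deqn{v_{free} = (T - \sum_{c \ne free} v_c A_c) / A_{free}.}
#'
#' @param target_total known total population, animals.
#' @param free_class class id whose density value is solved.
#' @param fixed_values named numeric: density value (animals/km^2) per fixed
#'   class id.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(target_total = 30e6, free_class = 1L,
                             fixed_values = c("2" = 5.8, "3" = 11.6,
                                              "4" = 17.4)) {
  stopifnot(is.numeric(target_total), length(target_total) == 1L,
            !is.null(names(fixed_values)))
  if (as.character(free_class) %in% names(fixed_values))
    stop("the free class cannot also carry a fixed value")
  structure(list(target_total = target_total,
                 free_class = as.integer(free_class),
                 fixed_values = fixed_values),
            class = "calibration_spec")
}

# national class areas (km^2) from a zonal table or a ready-made table
national_class_areas <- function(x) {
  if (inherits(x, "zonal_table")) x <- x$areas
  stopifnot(all(c("class_id", "area_km2") %in% names(x)))
  out <- stats::aggregate(area_km2 ~ class_id, x, sum)
  stats::setNames(out$area_km2, out$class_id)
}

#' Solve the free class density value
#'
#' Exact linear solve of the calibration identity above. A negative solution
#' is returned with a warning (the target is unreachable given the fixed
#' contributions); a zero free-class area is an error.
#'
#' @param zt a [zonal_table][zonal_class_areas()] or a data.frame with
#'   `class_id`, `area_km2`.
#' @param spec a [calibration_spec].
#' @return The solved density value (animals/km^2).
#' @export
calibrate_free_class <- function(zt, spec = calibration_spec()) {
  areas <- national_class_areas(zt)
  free <- as.character(spec$free_class)
  a_free <- if (free %in% names(areas)) areas[[free]] else 0
  if (a_free <= 0)
    stop("free class ", free, " has zero area: calibration is unsolvable")
  fixed <- spec$fixed_values
  contrib <- sum(vapply(names(fixed), function(cl) {
    if (cl %in% names(areas)) fixed[[cl]] * areas[[cl]] else 0
  }, numeric(1)))
  v <- (spec$target_total - contrib) / a_free
  if (v < 0)
    warning(sprintf("calibrated value is negative (%.4g): target below fixed contributions", v))
  v
}

#' Population and density estimates from class areas
#'
#' Population is linear in the legend's density values:
#' \eqn{P = \sum_c A_c v_c} over density classes, at unit, state or national
#' level. Statewide density divides by the state's official total area (sum
#' of its units' official areas, supplied by the zone layer); presence
#' density divides by the summed area of presence classes only.
#'
#' @param zt a [zonal_table][zonal_class_areas()].
#' @param legend a [map_legend]; defaults to the table's. Every density
#'   class present in the areas must carry a non-missing density value.
#' @param level `"unit"`, `"state"` or `"national"`.
#' @return data.frame of class `state_summary` with `population`,
#'   `total_area_km2`, `presence_area_km2`, `statewide_density` and
#'   `presence_density` per row (plus the id column for the level).
#' @export
estimate_population <- function(zt, legend = zt$legend,
                                level = c("state", "unit", "national")) {
  level <- match.arg(level)
  stopifnot(inherits(zt, "zonal_table"))
  lg <- legend$classes
  dens <- lg$class_id[lg$role == "density"]
  used <- intersect(unique(zt$areas$class_id), dens)
  vals <- lg$density[match(used, lg$class_id)]
  if (anyNA(vals))
    stop("missing density value for class(es): ",
         paste(used[is.na(vals)], collapse = ", "),
         " (calibrate or set the legend value first)")
  presence <- lg$class_id[lg$presence]

  a <- zt$areas
  a$pop <- ifelse(a$class_id %in% dens,
                  a$area_km2 * lg$density[match(a$class_id, lg$class_id)], 0)
  a$pres <- ifelse(a$class_id %in% presence, a$area_km2, 0)

  key <- switch(level, unit = a$unit_id, state = a$state_id,
                national = rep("national", nrow(a)))
  pop <- rowsum(a$pop, key)
  pres <- rowsum(a$pres, key)
  ids <- rownames(pop)

  uofficial <- zt$units$official_area_km2
  total <- switch(level,
    unit = uofficial[match(ids, zt$units$unit_id)],
    state = as.vector(rowsum(uofficial, zt$units$state_id)[ids, ]),
    national = sum(uofficial))

  out <- data.frame(id = ids, population = as.vector(pop),
                    total_area_km2 = total,
                    presence_area_km2 = as.vector(pres))
  out$statewide_density <- out$population / out$total_area_km2
  out$presence_density <- ifelse(out$presence_area_km2 > 0,
                                 out$population / out$presence_area_km2, NA)
  names(out)[1] <- switch(level, unit = "unit_id", state = "state_id",
                          national = "level")
  rownames(out) <- NULL
  class(out) <- c("state_summary", "data.frame")
  out
}

#' National presence-area density
#'
#' Total population divided by total presence area, reported at 0.1
#' precision (animals/km^2).
#' @param population total population (animals) or vector to sum.
#' @param presence_area total presence-class area (km^2) or vector to sum.
#' @return density rounded to 0.1.
#' @export
national_presence_density <- function(population, presence_area) {
  p <- sum(population); a <- sum(presence_area)
  if (a <= 0) stop("zero presence area")
  round(p / a, 1)
}

#' Compare reported estimates with map-derived estimates
#'
#' Per matched state: `difference = reported - map_estimate` and
#' `quotient = reported / map_estimate` (quotient reported at 2 decimals,
#' undefined when the map estimate is 0). Totals and the mean absolute
#' error are computed over matched states; unmatched states are excluded and
#' listed in the `unmatched` attribute.
#'
#' @param reported data.frame `state`, `estimate` (agency-reported).
#' @param map_est data.frame `state`, `estimate` (map-derived).
#' @return data.frame of class `comparison_table` with attributes
#'   `totals` (reported, map, difference), `mae` and `unmatched`.
#' @export
compare_estimates <- function(reported, map_est) {
  stopifnot(all(c("state", "estimate") %in% names(reported)),
            all(c("state", "estimate") %in% names(map_est)))
  states <- intersect(reported$state, map_est$state)
  if (!length(states)) stop("no states in common between the two tables")
  r <- reported$estimate[match(states, reported$state)]
  m <- map_est$estimate[match(states, map_est$state)]
  out <- data.frame(state = states, reported = r, map_estimate = m,
                    difference = r - m,
                    quotient = ifelse(m > 0, round(r / m, 2), NA))
  attr(out, "totals") <- c(reported = sum(r), map_estimate = sum(m),
                           difference = sum(r) - sum(m))
  attr(out, "mae") <- mean(abs(r - m))
  attr(out, "unmatched") <- list(
    reported_only = setdiff(reported$state, states),
    map_only = setdiff(map_est$state, states))
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  t <- attr(x, "totals")
  cat(sprintf("Totals: reported %.0f, map %.0f, difference %.0f; MAE %.0f\n",
              t["reported"], t["map_estimate"], t["difference"],
              attr(x, "mae")))
  invisible(x)
}

#' Mean and sample SD of multi-year agency estimates
#'
#' Agencies re-estimate populations yearly; the map is compared against the
#' mean of the available years, with the sample standard deviation (n-1
#' denominator) as the reporting spread. Missing years are dropped.
#'
#' @param values numeric vector of yearly estimates (NAs dropped).
#' @return list `mean`, `sd` (NA for a single value), `n`.
#' @export
annual_stats <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("no values")
  list(mean = mean(v), sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
       n = length(v))
}

#' Count states at or above a density threshold
#'
#' Densities are compared after rounding to 0.1 (the reporting precision),
#' so a state printed at exactly the threshold counts.
#' @param summary a [state_summary][estimate_population()] or data.frame
#'   with a `statewide_density` column.
#' @param threshold animals/km^2.
#' @return integer count.
#' @export
count_states_at_or_above <- function(summary, threshold) {
  sum(round(summary$statewide_density, 1) >= threshold)
}

#' Bundled regression tables
#'
#' Transcriptions of published state-level deer summaries shipped with the
#' package for regression-testing the demography arithmetic:
#' `"state_density"` (1982/2003 population, statewide density and presence
#' area by state), `"qdma"` (2005 agency-reported estimates vs the 2003 map
#' for 25 states) and `"sdsg"` (four annual southeastern agency estimates,
#' 2001-2005, vs the 2003 map for 16 states).
#'
#' @param name one of `"state_density"`, `"qdma"`, `"sdsg"`.
#' @return data.frame.
#' @export
bundled_table <- function(name = c("state_density", "qdma", "sdsg")) {
  name <- match.arg(name)
  file <- switch(name, state_density = "state_density_1982_2003.csv",
                 qdma = "qdma_2005_comparison.csv",
                 sdsg = "sdsg_annual_estimates.csv")
  utils::read.csv(system.file("extdata", file, package = "mapreclaim",
                              mustWork = TRUE), stringsAsFactors = FALSE)
}
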