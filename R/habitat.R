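#' Natural-breaks thresholds for habitability classes
#'
#' Fits Fisher-Jenks optimal 1-D breaks: the partition of the (sorted) values
#' into `n_classes` contiguous groups minimizing the total within-class sum
#' of squared deviations, found exactly by dynamic programming. Each break is
#' the smallest value of its upper class, so classifying with the left-closed
#' convention of [classify_suitability()] reproduces the fitted partition.
#' Large rasters are subsampled (seeded) before fitting.
#'
#' @param values Numeric vector (e.g. a suitability raster); `NA` ignored.
#' @param n_classes Number of classes (default 4).
#' @param max_sample Subsample cap for fitting (default 10000).
#' @param seed Seed for the subsample.
#' @param source Label for the scenario the breaks were fitted on.
#' @return An object of class `break_set`: `breaks` (length
#'   `n_classes - 1`, strictly increasing), `n_classes`, `ssd`, `n_used`,
#'   `source`.
#' @export
jenks_breaks <- function(values, n_classes = 4, max_sample = 10000, seed = 1,
                         source = "current") {
  v <- values[!is.na(values)]
  stopifnot(n_classes >= 2)
  if (length(unique(v)) < n_classes)
    stop("need at least ", n_classes, " distinct values for ", n_classes,
         " classes")
  if (length(v) > max_sample) {
    set.seed(seed)
    v <- sample(v, max_sample)
    # guard: a subsample can lose distinctness only in pathological rasters
    if (length(unique(v)) < n_classes)
      stop("subsample has fewer distinct values than classes; raise max_sample")
  }
  v <- sort(v)
  starts <- jenks_dp(v, as.integer(n_classes))
  breaks <- v[starts[-1]]
  if (any(diff(breaks) <= 0))
    stop("tied values straddle a class boundary; breaks are not strictly ",
         "increasing")
  structure(list(breaks = breaks, n_classes = as.integer(n_classes),
                 ssd = attr(starts, "ssd"), n_used = length(v),
                 source = source),
            class = "break_set")
}

#' @export
print.break_set <- function(x, ...) {
  cat(sprintf("<break_set> %d classes on %d values (%s): %s (ssd %.4g)\n",
              x$n_classes, x$n_used, x$source,
              paste(signif(x$breaks, 4), collapse = " | "), x$ssd))
  invisible(x)
}

#' Classify suitability into habitability zones
#'
#' Maps each cell to one of four classes by the break set, left-closed on the
#' upper classes (a value exactly equal to a break goes up): `non` if
#' `p < b1`, `low` if `b1 <= p < b2`, `medium` if `b2 <= p < b3`, `high` if
#' `p >= b3`. Masked cells stay masked.
#'
#' @param suitability A `suitability_map` (or a bare numeric matrix).
#' @param breaks A `break_set` with three breaks.
#' @return A `habitat_class_map`: integer matrix with codes 0 (non) to
#'   3 (high), `NA` on the mask, plus the break set and map labels.
#' @export
classify_suitability <- function(suitability, breaks) {
  stopifnot(inherits(breaks, "break_set"))
  vals <- if (inherits(suitability, "suitability_map")) suitability$values
          else suitability
  cls <- matrix(NA_integer_, nrow(vals), ncol(vals))
  ok <- !is.na(vals)
  cls[ok] <- rowSums(outer(vals[ok], breaks$breaks, `>=`))
  meta <- if (inherits(suitability, "suitability_map"))
    suitability[c("grid", "species", "scenario", "horizon")] else
    list(grid = NULL, species = NA, scenario = NA, horizon = NA)
  structure(c(list(classes = cls, breaks = breaks), meta),
            class = "habitat_class_map")
}

#' Class labels of a habitat class map
#' @param classmap A `habitat_class_map`.
#' @return Factor matrix codes: `non`, `low`, `medium`, `high`.
#' @export
habitat_class_labels <- function(classmap) {
  c("non", "low", "medium", "high")[classmap$classes + 1L]
}

#' @export
print.habitat_class_map <- function(x, ...) {
  tab <- table(factor(habitat_class_labels(x),
                      levels = c("non", "low", "medium", "high")))
  cat(sprintf("<habitat_class_map> %s [%s/%s]: %s\n", x$species, x$scenario,
              x$horizon,
              paste(names(tab), as.integer(tab), sep = "=", collapse = " ")))
  invisible(x)
}

#' Construct a binary range from flagged cells
#' @param grid An `nc_grid`.
#' @param flags Logical matrix of presence cells (`NA` treated as `FALSE`).
#' @return A `binary_range` with geodesic `area_km2`.
#' @export
binary_range <- function(grid, flags) {
  flags[is.na(flags)] <- FALSE
  lat <- row_center_lat(grid)
  area_w <- matrix(cell_area(lat, grid$res_arcmin), grid$n_rows, grid$n_cols)
  structure(list(grid = grid, flags = flags,
                 area_km2 = sum(area_w[flags])),
            class = "binary_range")
}

#' Collapse habitability classes to a presence/absence range
#'
#' The potential distribution range is the union of the low, medium and high
#' habitability zones; only `non` cells (and masked cells) fall outside it.
#' Area is the geodesic sum of flagged cell areas.
#'
#' @param classmap A `habitat_class_map` with an `nc_grid`.
#' @return A `binary_range`: grid, logical `flags`, `area_km2`.
#' @export
to_binary_range <- function(classmap) {
  stopifnot(inherits(classmap, "habitat_class_map"),
            inherits(classmap$grid, "nc_grid"))
  binary_range(classmap$grid, !is.na(classmap$classes) & classmap$classes >= 1L)
}

#' @export
print.binary_range <- function(x, ...) {
  cat(sprintf("<binary_range> %d cell(s), %.4g km^2\n",
              sum(x$flags), x$area_km2))
  invisible(x)
}

#' Write a habitat class map as an ASCII grid (codes 0-3)
#' @param classmap A `habitat_class_map` carrying an `nc_grid`.
#' @param path Output path.
#' @export
write_class_map <- function(classmap, path) {
  write_ascii_grid(classmap$classes, classmap$grid, path)
}
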