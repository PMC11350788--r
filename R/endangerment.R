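#' Ordered IUCN-style threat categories
#'
#' The six threat levels form a total order `LC < NT < VU < EN < CR < EX`
#' (codes 0-5); `DD` (Data Deficient) sits outside the order.
#'
#' @format Character vector of category codes in threat order.
#' @export
IUCN_LEVELS <- c("LC", "NT", "VU", "EN", "CR", "EX")

iucn_rank <- function(category) {
  r <- match(category, IUCN_LEVELS) - 1L
  if (anyNA(r) && !all(category[is.na(r)] == "DD"))
    stop("unknown IUCN category: ",
         paste(unique(category[is.na(r) & category != "DD"]), collapse = ", "))
  r
}

#' Range change between two binary ranges
#'
#' Loss fraction `L = (A_current - A_future) / A_current` with geodesic
#' areas; `L` is negative when the range expands and at most 1.
#'
#' @param current,future `binary_range`s on the same grid.
#' @param species,scenario,horizon Labels recorded on the result.
#' @return A `range_change`: areas, `loss_fraction`, labels.
#' @export
loss_fraction <- function(current, future, species = NA_character_,
                          scenario = NA_character_, horizon = NA_character_) {
  stopifnot(inherits(current, "binary_range"), inherits(future, "binary_range"))
  if (!grids_equal(current$grid, future$grid))
    stop("ranges live on different grids")
  if (current$area_km2 <= 0)
    stop("current range has zero area; assess this species on the ",
         "data-poor path")
  structure(list(species = species, scenario = scenario, horizon = horizon,
                 area_current_km2 = current$area_km2,
                 area_future_km2 = future$area_km2,
                 loss_fraction =
                   (current$area_km2 - future$area_km2) / current$area_km2),
            class = "range_change")
}

#' @export
print.range_change <- function(x, ...) {
  cat(sprintf("<range_change> %s [%s/%s]: %.4g -> %.4g km^2 (L = %+.3f)\n",
              x$species, x$scenario, x$horizon, x$area_current_km2,
              x$area_future_km2, x$loss_fraction))
  invisible(x)
}

#' Map a projected range-loss fraction to a threat category
#'
#' The range-loss reading of IUCN criterion A3(c): `EX` for total loss
#' (`L = 1`, within a 1e-12 tolerance absorbing floating-point area sums),
#' `CR` for loss of at least 80%, `EN` at least 50%, `VU` at least 30%, `NT`
#' at least 10%, and `LC` otherwise — including every expansion (`L < 0`).
#'
#' @param L Loss fraction(s), each at most 1.
#' @return Character vector of category codes.
#' @export
classify_loss <- function(L) {
  stopifnot(all(L <= 1 + 1e-9))
  out <- rep("LC", length(L))
  out[L >= 0.1] <- "NT"
  out[L >= 0.3] <- "VU"
  out[L >= 0.5] <- "EN"
  out[L >= 0.8] <- "CR"
  out[L >= 1 - 1e-12] <- "EX"
  out
}

#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param p1,p2 Numeric `c(lon, lat)` in decimal degrees.
#' @return Distance in km.
#' @export
distance_km <- function(p1, p2) {
  to_rad <- pi / 180
  lat1 <- p1[2] * to_rad; lat2 <- p2[2] * to_rad
  dlat <- (p2[2] - p1[2]) * to_rad
  dlon <- (p2[1] - p1[1]) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1) * cos(lat2) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Area of the triangle spanned by three occurrence points
#'
#' Planar triangle area under an equirectangular projection centered at the
#' points' mean latitude — adequate at the scales where the three-record rule
#' applies. Collinear or duplicated points give area 0 (with a warning for
#' duplicates).
#'
#' @param three_points 3 x 2 matrix (or data frame) of `lon`, `lat` rows.
#' @return Area in km^2.
#' @export
polygon_area_km2 <- function(three_points) {
  p <- as.matrix(three_points)
  stopifnot(nrow(p) == 3, ncol(p) >= 2)
  if (anyDuplicated(round(p[, 1:2], 12))) {
    warning("duplicate points; area is 0")
    return(0)
  }
  km_per_deg <- 6371 * pi / 180
  lat0 <- mean(p[, 2])
  x <- p[, 1] * km_per_deg * cos(lat0 * pi / 180)
  y <- p[, 2] * km_per_deg
  abs((x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])) / 2
}

#' Threat-level elevation for data-poor species
#'
#' Species with too few records for a distribution model are assessed from
#' record geometry. With three records, by the enclosed triangle area:
#' below 100 km^2 elevate 3 levels, below 500 km^2 2 levels, below
#' 10,000 km^2 1 level. With two records, by the distance between them:
#' below 10 km 3 levels, below 50 km 2 levels, below 500 km 1 level. A single
#' record always elevates 3 levels.
#'
#' @param n_records 1, 2 or 3.
#' @param geometry For `n_records = 3` the 3-point matrix (or a precomputed
#'   area in km^2); for `n_records = 2` the 2 x 2 point matrix (or a
#'   precomputed distance in km); ignored for a single record.
#' @return List: `levels` (0-3) and the `statistic` (area or distance) used.
#' @export
data_poor_levels <- function(n_records, geometry = NULL) {
  if (!n_records %in% 1:3)
    stop("the data-poor cascade applies to 1-3 records; ",
         "4 or more records take the model path")
  if (n_records == 1)
    return(list(levels = 3L, statistic = NA_real_))
  if (n_records == 3) {
    a <- if (is.numeric(geometry) && length(geometry) == 1) geometry
         else polygon_area_km2(geometry)
    lv <- if (a < 100) 3L else if (a < 500) 2L else if (a < 10000) 1L else 0L
    return(list(levels = lv, statistic = a))
  }
  d <- if (is.numeric(geometry) && length(geometry) == 1) geometry
       else {
         g <- as.matrix(geometry)
         distance_km(g[1, 1:2], g[2, 1:2])
       }
  lv <- if (d < 10) 3L else if (d < 50) 2L else if (d < 500) 1L else 0L
  list(levels = lv, statistic = d)
}

#' Elevate a threat category by a number of levels
#'
#' Moves up the threat order, capped at `CR`: `EX` is reserved for species
#' losing their entire modeled range, so a geometry rule alone can never
#' declare an extinction.
#'
#' @param category A threat category (not `DD`).
#' @param levels Number of levels to elevate (0-3).
#' @return The elevated category code.
#' @export
elevate <- function(category, levels) {
  stopifnot(levels >= 0, levels <= 3, category %in% IUCN_LEVELS)
  r <- min(iucn_rank(category) + as.integer(levels), iucn_rank("CR"))
  IUCN_LEVELS[r + 1L]
}

#' Assess one species for one scenario and horizon
#'
#' Routes the species down the model-based path (loss fraction of its
#' modeled binary ranges) or the data-poor path (record-geometry elevation
#' from a baseline category). Data-poor assessments are assumed constant
#' across horizons: the caller reuses the first horizon's assessment (see
#' [run_assessment()]).
#'
#' @param species Species id.
#' @param scenario,horizon Labels.
#' @param current_range,future_range `binary_range`s (model path), or `NULL`.
#' @param records Data frame of the species' records (data-poor path).
#' @param baseline Baseline category the data-poor cascade elevates from
#'   (default `"LC"`; override with the species' current IUCN listing).
#' @return A one-row data frame: species, scenario, horizon, `path`,
#'   `loss_fraction`, `statistic`, `levels_elevated`, `category`,
#'   `expansion` flag.
#' @export
assess_species <- function(species, scenario, horizon,
                           current_range = NULL, future_range = NULL,
                           records = NULL, baseline = "LC") {
  row <- data.frame(species = species, scenario = scenario, horizon = horizon,
                    path = NA_character_, loss_fraction = NA_real_,
                    statistic = NA_real_, levels_elevated = 0L,
                    category = "DD", expansion = FALSE,
                    stringsAsFactors = FALSE)
  model_ok <- !is.null(current_range) && !is.null(future_range) &&
    current_range$area_km2 > 0
  if (model_ok) {
    rc <- loss_fraction(current_range, future_range, species, scenario, horizon)
    row$path <- "model_based"
    row$loss_fraction <- rc$loss_fraction
    row$category <- classify_loss(rc$loss_fraction)
    row$expansion <- rc$loss_fraction < 0
    return(row)
  }
  n <- if (is.null(records)) 0L else nrow(records)
  if (n < 1) return(row)  # no usable inputs: Data Deficient
  n <- min(n, 3L)
  geom <- if (n >= 2) as.matrix(records[seq_len(n), c("lon", "lat")]) else NULL
  dp <- data_poor_levels(n, geom)
  row$path <- c("data_poor_single", "data_poor_distance",
                "data_poor_area")[n]
  row$statistic <- dp$statistic
  row$levels_elevated <- dp$levels
  row$category <- elevate(baseline, dp$levels)
  row
}

#' Tabulate category transitions
#'
#' Counts species by (baseline category, projected category) for one
#' scenario/horizon — the numbers behind an alluvial threat-category plot.
#'
#' @param assessments Data frame with columns `species` and `category`.
#' @param baseline_categories Named vector (species -> current category);
#'   species without a baseline count from `DD`.
#' @return A contingency table `from` x `to` over `DD` + the six levels.
#' @export
transition_table <- function(assessments, baseline_categories) {
  lv <- c("DD", IUCN_LEVELS)
  from <- baseline_categories[assessments$species]
  from[is.na(from)] <- "DD"
  table(from = factor(from, levels = lv),
        to = factor(assessments$category, levels = lv))
}

#' Species richness on a one-degree grid
#'
#' A species is counted in a one-degree cell when any flagged cell of its
#' native-resolution binary range overlaps that cell.
#'
#' @param ranges Named list of `binary_range`s (one per species), all on one
#'   native grid.
#' @param degree Cell size of the richness grid in degrees (default 1).
#' @return A `richness_map`: a one-degree `nc_grid` covering the native grid
#'   and an integer matrix of per-cell species counts.
#' @export
richness_map <- function(ranges, degree = 1) {
  stopifnot(length(ranges) >= 1)
  g <- ranges[[1]]$grid
  coarse <- nc_grid(g$west, g$south, degree * 60,
                    ceiling(round(g$n_rows * g$res_deg / degree, 9)),
                    ceiling(round(g$n_cols * g$res_deg / degree, 9)))
  counts <- matrix(0L, coarse$n_rows, coarse$n_cols)
  for (br in ranges) {
    if (!grids_equal(br$grid, g)) stop("ranges live on different grids")
    cells <- which(br$flags)
    if (!length(cells)) next
    hit <- matrix(FALSE, coarse$n_rows, coarse$n_cols)
    row <- cell_row(g, cells); col <- cell_col(g, cells)
    # native cell bounds -> coarse cell index ranges they intersect
    s <- g$south + (row - 1) * g$res_deg; n <- s + g$res_deg
    w <- g$west + (col - 1) * g$res_deg; e <- w + g$res_deg
    r0 <- pmax(1L, floor((s - coarse$south) / degree + 1e-9) + 1L)
    r1 <- pmin(coarse$n_rows, ceiling((n - coarse$south) / degree - 1e-9))
    c0 <- pmax(1L, floor((w - coarse$west) / degree + 1e-9) + 1L)
    c1 <- pmin(coarse$n_cols, ceiling((e - coarse$west) / degree - 1e-9))
    for (i in seq_along(cells))
      hit[r0[i]:r1[i], c0[i]:c1[i]] <- TRUE
    counts <- counts + hit
  }
  structure(list(grid = coarse, counts = counts), class = "richness_map")
}

#' @export
print.richness_map <- function(x, ...) {
  cat(sprintf("<richness_map> %d x %d cells, richness 0-%d\n",
              x$grid$n_rows, x$grid$n_cols, max(x$counts)))
  invisible(x)
}

#' Signed richness change between two richness maps
#' @param a,b `richness_map`s on the same grid (`b` the future one).
#' @return Integer matrix `b - a` per cell.
#' @export
richness_change <- function(a, b) {
  stopifnot(inherits(a, "richness_map"), inherits(b, "richness_map"),
            grids_equal(a$grid, b$grid))
  b$counts - a$counts
}
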