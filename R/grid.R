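#' Define a geographic raster grid
#'
#' A regular longitude/latitude grid on which all raster layers of a run are
#' co-registered. Rows run south to north, columns west to east; cell (1,1)
#' has its lower-left (south-west) corner at (`west`, `south`). Cells are
#' half-open intervals `[west, east) x [south, north)`, so a point exactly on
#' a shared edge belongs to the cell to its north-east.
#'
#' @param west,south Coordinates of the grid origin (decimal degrees).
#' @param res_arcmin Cell size in arc-minutes (both axes); must be positive.
#' @param n_rows,n_cols Number of rows (latitude) and columns (longitude).
#' @return An object of class `nc_grid`.
#' @examples
#' g <- nc_grid(-180, -90, res_arcmin = 120, n_rows = 90, n_cols = 180)
#' g
#' @export
nc_grid <- function(west, south, res_arcmin, n_rows, n_cols) {
  if (!is.finite(res_arcmin) || res_arcmin <= 0)
    stop("grid resolution must be a positive number of arc-minutes")
  if (n_rows < 1 || n_cols < 1)
    stop("grid must have at least one row and one column (zero-area extent)")
  res_deg <- res_arcmin / 60
  north <- south + n_rows * res_deg
  east  <- west + n_cols * res_deg
  if (north > 90 + 1e-9 || south < -90 - 1e-9)
    stop("grid extent exceeds [-90, 90] latitude")
  structure(
    list(west = west, south = south, res_arcmin = res_arcmin,
         res_deg = res_deg, n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols), east = east, north = north),
    class = "nc_grid")
}

#' @export
print.nc_grid <- function(x, ...) {
  cat(sprintf("<nc_grid> %d x %d cells, %.3g arc-min (%.4g deg)\n",
              x$n_rows, x$n_cols, x$res_arcmin, x$res_deg))
  cat(sprintf("  extent: lon [%.4g, %.4g], lat [%.4g, %.4g]\n",
              x$west, x$east, x$south, x$north))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  abs(a$west - b$west) < tol && abs(a$south - b$south) < tol &&
    abs(a$res_arcmin - b$res_arcmin) < tol &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Latitude of row centers
#' @param grid An `nc_grid`.
#' @return Numeric vector of length `n_rows`, south to north.
#' @export
row_center_lat <- function(grid) {
  grid$south + (seq_len(grid$n_rows) - 0.5) * grid$res_deg
}

col_center_lon <- function(grid) {
  grid$west + (seq_len(grid$n_cols) - 0.5) * grid$res_deg
}

#' Map point coordinates to grid cell indices
#'
#' Uses the half-open cell convention `[west, east) x [south, north)`.
#' Points outside the grid extent map to `NA`.
#'
#' @param grid An `nc_grid`.
#' @param lon,lat Coordinate vectors (decimal degrees).
#' @return Integer vector of linear cell indices (column-major over the
#'   `n_rows` x `n_cols` layer matrix), `NA` for points off the grid.
#' @export
cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$west) / grid$res_deg) + 1
  row <- floor((lat - grid$south) / grid$res_deg) + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  idx <- ifelse(ok, (col - 1L) * grid$n_rows + row, NA_integer_)
  as.integer(idx)
}

cell_row <- function(grid, cells) ((cells - 1L) %% grid$n_rows) + 1L
cell_col <- function(grid, cells) ((cells - 1L) %/% grid$n_rows) + 1L

#' Coordinates of cell centers
#' @param grid An `nc_grid`.
#' @param cells Linear cell indices.
#' @return Data frame with `lon` and `lat` of each cell center.
#' @export
cell_center <- function(grid, cells) {
  data.frame(
    lon = grid$west + (cell_col(grid, cells) - 0.5) * grid$res_deg,
    lat = grid$south + (cell_row(grid, cells) - 0.5) * grid$res_deg)
}

#' Geodesic area of a grid cell
#'
#' Area of a `res_arcmin` x `res_arcmin` cell centered at latitude
#' `lat_center` on a sphere of radius 6371 km:
#' `A = R^2 * dlambda * (sin(phi_n) - sin(phi_s))`, with `dlambda` the cell
#' width in radians and `phi_n`, `phi_s` the north/south cell edges.
#'
#' @param lat_center Latitude of the cell center (degrees); vectorized.
#' @param res_arcmin Cell size in arc-minutes.
#' @return Cell area in square kilometers.
#' @examples
#' cell_area(0, 60)  # 1-degree cell on the equator, ~12364 km^2
#' @export
cell_area <- function(lat_center, res_arcmin) {
  stopifnot(all(abs(lat_center) <= 90 + 1e-9))
  R <- 6371
  res_deg <- res_arcmin / 60
  half <- res_deg / 2
  phi_n <- pmin(lat_center + half, 90) * pi / 180
  phi_s <- pmax(lat_center - half, -90) * pi / 180
  R^2 * (res_deg * pi / 180) * (sin(phi_n) - sin(phi_s))
}

#' Assemble a climate stack
#'
#' A named set of raster layers (bioclimatic variables, altitude, ...) sharing
#' one grid and one nodata mask, tagged with scenario and horizon labels.
#' Layers are `n_rows x n_cols` matrices with `NA` marking nodata cells.
#'
#' @param grid An `nc_grid`.
#' @param layers Named list of numeric matrices, all `n_rows x n_cols`.
#' @param scenario,horizon Labels, e.g. `"current"` or `"SSP2-4.5"` / `"2050s"`.
#' @return An object of class `climate_stack`.
#' @export
climate_stack <- function(grid, layers, scenario = "current", horizon = "current") {
  stopifnot(inherits(grid, "nc_grid"), length(layers) >= 1,
            !is.null(names(layers)), all(nzchar(names(layers))))
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || nrow(m) != grid$n_rows || ncol(m) != grid$n_cols)
      stop(sprintf("layer '%s' does not match the grid (%d x %d)",
                   nm, grid$n_rows, grid$n_cols))
  }
  # shared mask: a cell is usable only where every layer has data
  na_any <- Reduce(`|`, lapply(layers, is.na))
  if (any(na_any)) layers <- lapply(layers, function(m) { m[na_any] <- NA; m })
  structure(list(grid = grid, layers = layers, scenario = scenario,
                 horizon = horizon), class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("<climate_stack> %s / %s: %d layer(s) [%s]\n", x$scenario,
              x$horizon, length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  print(x$grid)
  invisible(x)
}

#' Unmasked cell indices of a stack
#' @param stack A `climate_stack`.
#' @return Integer vector of linear indices of cells with data in all layers.
#' @export
unmasked_cells <- function(stack) {
  which(!is.na(stack$layers[[1]]))
}

#' Extract layer values at cells
#' @param stack A `climate_stack`.
#' @param cells Linear cell indices.
#' @param variables Layer names (default: all).
#' @return Numeric matrix, one row per cell, one column per variable.
#' @export
stack_values <- function(stack, cells, variables = names(stack$layers)) {
  missing_v <- setdiff(variables, names(stack$layers))
  if (length(missing_v))
    stop("stack has no layer(s): ", paste(missing_v, collapse = ", "))
  out <- vapply(variables, function(v) stack$layers[[v]][cells],
                numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1,
                                         dimnames = list(NULL, variables))
  out
}

# ---- plain-text raster I/O (ESRI ASCII grid) --------------------------------

#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text, single-band georeferenced format readable by standard GIS
#' tools. Rows are written north to south as the format requires.
#'
#' @param layer Numeric matrix (rows south to north, as stored in a stack).
#' @param grid The `nc_grid` the layer lives on.
#' @param path Output file path.
#' @param nodata Value standing in for `NA` cells.
#' @export
write_ascii_grid <- function(layer, grid, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$west),
    sprintf("yllcorner %.10g", grid$south),
    sprintf("cellsize %.10g", grid$res_deg),
    sprintf("NODATA_value %g", nodata)), con)
  m <- layer
  m[is.na(m)] <- nodata
  for (r in rev(seq_len(nrow(m))))   # north first
    writeLines(paste(format(m[r, ], trim = TRUE, digits = 10), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path File written by [write_ascii_grid()] or any conforming tool.
#' @return List with `layer` (matrix, rows south to north) and `grid`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("not an ASCII grid: ", path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  n_rows <- hdr$nrows; n_cols <- hdr$ncols
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != n_rows * n_cols)
    stop("ASCII grid body has wrong cell count")
  m <- matrix(body, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m <- m[rev(seq_len(n_rows)), , drop = FALSE]  # back to south-first rows
  m[m == hdr$nodata_value] <- NA
  grid <- nc_grid(hdr$xllcorner, hdr$yllcorner, hdr$cellsize * 60,
                  n_rows, n_cols)
  list(layer = m, grid = grid)
}

#' Read a climate stack from ASCII grid files
#'
#' Assembles co-registered single-band rasters into a stack, rejecting
#' layers whose grids disagree.
#'
#' @param paths Character vector of ASCII grid files.
#' @param labels Layer names, one per path.
#' @param scenario,horizon Stack labels.
#' @return A `climate_stack`.
#' @export
read_stack <- function(paths, labels, scenario = "current", horizon = "current") {
  stopifnot(length(paths) == length(labels), length(paths) >= 1)
  first <- read_ascii_grid(paths[1])
  layers <- stats::setNames(vector("list", length(paths)), labels)
  layers[[1]] <- first$layer
  if (length(paths) > 1) for (i in 2:length(paths)) {
    nxt <- read_ascii_grid(paths[i])
    if (!grids_equal(first$grid, nxt$grid))
      stop(sprintf(
        "grid mismatch: '%s' is %dx%d @ %.4g arc-min but '%s' is %dx%d @ %.4g arc-min",
        labels[1], first$grid$n_rows, first$grid$n_cols, first$grid$res_arcmin,
        labels[i], nxt$grid$n_rows, nxt$grid$n_cols, nxt$grid$res_arcmin))
    layers[[i]] <- nxt$layer
  }
  climate_stack(first$grid, layers, scenario, horizon)
}

#' Write every layer of a stack as ASCII grids
#' @param stack A `climate_stack`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
write_stack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(stack$layers)) {
    p <- file.path(dir, sprintf("%s_%s_%s.asc", nm, stack$scenario, stack$horizon))
    write_ascii_grid(stack$layers[[nm]], stack$grid, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
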