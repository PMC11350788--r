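#' Generate a synthetic multi-layer climate surface
#'
#' Builds smooth, seeded climate layers on a grid: each layer is the sum of a
#' latitudinal gradient, a low-frequency sinusoid in longitude and latitude,
#' and white noise. The first layer ("var1") is temperature-like: it peaks at
#' the equator and falls off toward the poles, the strongest real-world
#' feature a bioclimatic stack carries. Optionally a near-duplicate of the
#' first layer is appended to exercise collinearity screening.
#'
#' @param grid An `nc_grid` (see [nc_grid()]).
#' @param n_variables Number of independent layers (>= 2).
#' @param seed Integer seed; identical seed and spec give identical stacks.
#' @param inject_duplicate If `TRUE`, append layer `"var1_dup"` equal to the
#'   first layer plus Gaussian noise of sd `duplicate_noise_sd`.
#' @param duplicate_noise_sd Noise sd of the injected duplicate (0 = copy).
#' @param noise_sd Sd of the white-noise component of each layer.
#' @return A `climate_stack` labelled `current`.
#' @export
generate_climate <- function(grid, n_variables = 3, seed = 1,
                             inject_duplicate = FALSE,
                             duplicate_noise_sd = 0.5, noise_sd = 0.3) {
  stopifnot(inherits(grid, "nc_grid"), n_variables >= 2)
  set.seed(seed)
  lat <- row_center_lat(grid)
  lon <- col_center_lon(grid)
  lat_m <- matrix(lat, grid$n_rows, grid$n_cols)
  lon_m <- matrix(lon, grid$n_rows, grid$n_cols, byrow = TRUE)
  layers <- list()
  for (v in seq_len(n_variables)) {
    if (v == 1) {
      # temperature-like: ~30 degC at the equator, decreasing poleward
      base <- 30 - 0.65 * abs(lat_m)
      amp <- 2
    } else {
      slope <- stats::runif(1, -0.3, 0.3)
      base <- stats::runif(1, 0, 50) + slope * lat_m
      amp <- stats::runif(1, 3, 8)
    }
    freq_lon <- stats::runif(1, 0.5, 2)
    freq_lat <- stats::runif(1, 0.5, 2)
    phase <- stats::runif(2, 0, 2 * pi)
    wave <- amp * sin(freq_lon * lon_m * pi / 180 + phase[1]) *
      cos(freq_lat * lat_m * pi / 180 + phase[2])
    noise <- matrix(stats::rnorm(grid$n_rows * grid$n_cols, sd = noise_sd),
                    grid$n_rows, grid$n_cols)
    layers[[paste0("var", v)]] <- base + wave + noise
  }
  if (inject_duplicate) {
    dup_noise <- matrix(stats::rnorm(grid$n_rows * grid$n_cols,
                                     sd = duplicate_noise_sd),
                        grid$n_rows, grid$n_cols)
    layers[["var1_dup"]] <- layers[["var1"]] + dup_noise
  }
  climate_stack(grid, layers, scenario = "current", horizon = "current")
}

#' Construct a scenario delta
#'
#' A per-variable additive shift standing in for a future-scenario climate
#' surface (e.g. a GCM projection under a given emissions pathway).
#'
#' @param shifts Named numeric vector, e.g. `c(var1 = 2)`, in variable units.
#' @param label Scenario label, e.g. `"SSP2-4.5"`.
#' @param horizon Horizon label, e.g. `"2050s"`.
#' @return An object of class `scenario_delta`.
#' @export
scenario_delta <- function(shifts, label, horizon) {
  stopifnot(is.numeric(shifts), !is.null(names(shifts)))
  structure(list(shifts = shifts, label = label, horizon = horizon),
            class = "scenario_delta")
}

#' Apply a scenario delta to a climate stack
#'
#' Shifts each named variable cell-wise by its delta; untouched variables are
#' copied and the nodata mask is preserved.
#'
#' @param stack A `climate_stack`.
#' @param delta A `scenario_delta` whose variable names all exist in `stack`.
#' @return A new `climate_stack` labelled with the delta's scenario/horizon.
#' @export
apply_delta <- function(stack, delta) {
  stopifnot(inherits(stack, "climate_stack"), inherits(delta, "scenario_delta"))
  unknown <- setdiff(names(delta$shifts), names(stack$layers))
  if (length(unknown))
    stop("delta shifts unknown variable(s): ", paste(unknown, collapse = ", "))
  layers <- stack$layers
  for (v in names(delta$shifts)) layers[[v]] <- layers[[v]] + delta$shifts[[v]]
  climate_stack(stack$grid, layers, scenario = delta$label,
                horizon = delta$horizon)
}

#' Gaussian suitability of a climate surface for a niche
#'
#' `s(x) = exp(-1/2 (z(x) - mu)' Sigma^-1 (z(x) - mu))`, with `z(x)` the cell's
#' climate restricted to the niche variables. Equals 1 exactly at the niche
#' center.
#'
#' @param stack A `climate_stack`.
#' @param mu Named niche center (variable units); names select the layers used.
#' @param sigma Niche covariance matrix (positive definite), same order as `mu`.
#' @return Matrix of suitabilities in `(0, 1]`, `NA` on masked cells.
#' @export
niche_suitability <- function(stack, mu, sigma) {
  stopifnot(!is.null(names(mu)))
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != length(mu) || ncol(sigma) != length(mu))
    stop("sigma must be ", length(mu), " x ", length(mu))
  if (!isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-8)))
    stop("sigma must be symmetric")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev))
    stop("sigma is singular or not positive definite")
  cells <- unmasked_cells(stack)
  z <- stack_values(stack, cells, names(mu))
  d <- sweep(z, 2, mu)
  qf <- rowSums((d %*% solve(sigma)) * d)
  out <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  out[cells] <- exp(-0.5 * qf)
  out
}

#' Create a virtual species with known niche and true ranges
#'
#' The truth object for recovery tests: a Gaussian climatic niche plus a
#' suitability threshold `s_star` defining the species' true range (the
#' superlevel set of suitability) under the current climate and under each
#' supplied scenario stack.
#'
#' @param stack Current-scenario `climate_stack`.
#' @param mu Named niche center; see [niche_suitability()].
#' @param sigma Niche covariance (positive definite).
#' @param s_star Suitability threshold strictly inside (0, 1).
#' @param id Species identifier.
#' @param scenario_stacks Named list of future `climate_stack`s (names are
#'   scenario labels, e.g. `"SSP2-4.5_2050s"`).
#' @param n_records Number of presence records this species should emit.
#' @return An object of class `virtual_species` with element `true_range`:
#'   a named list of logical matrices (`current` plus one per scenario).
#' @export
make_virtual_species <- function(stack, mu, sigma, s_star, id,
                                 scenario_stacks = list(), n_records = 200) {
  if (!(s_star > 0 && s_star < 1)) stop("s_star must lie strictly in (0, 1)")
  suit <- niche_suitability(stack, mu, sigma)
  ranges <- list(current = !is.na(suit) & suit >= s_star)
  for (lbl in names(scenario_stacks)) {
    if (!grids_equal(stack$grid, scenario_stacks[[lbl]]$grid))
      stop("scenario stack '", lbl, "' is not on the base grid")
    s2 <- niche_suitability(scenario_stacks[[lbl]], mu, sigma)
    ranges[[lbl]] <- !is.na(s2) & s2 >= s_star
  }
  structure(list(id = id, mu = mu, sigma = as.matrix(sigma), s_star = s_star,
                 grid = stack$grid, suitability = suit, true_range = ranges,
                 n_records = as.integer(n_records)),
            class = "virtual_species")
}

#' @export
print.virtual_species <- function(x, ...) {
  cat(sprintf("<virtual_species> %s: %d-variable Gaussian niche, s* = %.3g\n",
              x$id, length(x$mu), x$s_star))
  for (nm in names(x$true_range))
    cat(sprintf("  true range [%s]: %d cells\n", nm, sum(x$true_range[[nm]])))
  invisible(x)
}

#' Sample presence records proportional to suitability
#'
#' Draws `n` cells (with replacement) with probability proportional to the
#' species' current-climate suitability and places one record at each drawn
#' cell's center. Supports `n` of 1-3 to exercise the data-poor assessment
#' path.
#'
#' @param vs A `virtual_species`.
#' @param n Number of records (>= 1).
#' @param seed Integer seed.
#' @return Data frame with columns `species`, `lon`, `lat`.
#' @export
sample_presences <- function(vs, n = vs$n_records, seed = 1) {
  stopifnot(inherits(vs, "virtual_species"), n >= 1)
  p <- vs$suitability
  cells <- which(!is.na(p) & p > 0)
  if (!length(cells) || sum(p[cells]) <= 0)
    stop("suitability is zero everywhere; cannot sample presences")
  set.seed(seed)
  drawn <- cells[sample.int(length(cells), n, replace = TRUE,
                            prob = p[cells])]
  ctr <- cell_center(vs$grid, drawn)
  data.frame(species = vs$id, lon = ctr$lon, lat = ctr$lat,
             stringsAsFactors = FALSE)
}

#' True range-loss fraction of a virtual species
#'
#' `(A_current - A_future) / A_current` with geodesic cell areas; negative
#' values mean expansion. This is the ground truth the assessment pipeline is
#' expected to recover.
#'
#' @param vs A `virtual_species`.
#' @param scenario_label Name of a scenario range stored in `vs$true_range`.
#' @return The loss fraction (a number <= 1).
#' @export
true_loss_fraction <- function(vs, scenario_label) {
  stopifnot(inherits(vs, "virtual_species"))
  if (!scenario_label %in% names(vs$true_range))
    stop("no true range for scenario '", scenario_label, "'")
  lat <- row_center_lat(vs$grid)
  area_w <- matrix(cell_area(lat, vs$grid$res_arcmin),
                   vs$grid$n_rows, vs$grid$n_cols)
  a_cur <- sum(area_w[vs$true_range$current])
  if (a_cur <= 0) stop("current true range has zero area")
  a_fut <- sum(area_w[vs$true_range[[scenario_label]]])
  (a_cur - a_fut) / a_cur
}

#' Serialize a virtual species' truth to JSON
#' @param vs A `virtual_species`.
#' @param path Output file.
#' @export
write_truth_json <- function(vs, path) {
  obj <- list(
    id = vs$id, mu = as.list(vs$mu), sigma = vs$sigma, s_star = vs$s_star,
    n_records = vs$n_records,
    range_cells = lapply(vs$true_range, function(m) which(m)),
    loss_fraction = stats::setNames(
      lapply(setdiff(names(vs$true_range), "current"),
             function(lbl) true_loss_fraction(vs, lbl)),
      setdiff(names(vs$true_range), "current")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
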