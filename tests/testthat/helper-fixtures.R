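# Small in-code fixtures shared across test files.

# A tiny 1-row landscape whose single layer takes prescribed values.
# Useful for moment-condition and oracle tests where every cell is background.
strip_stack <- function(values, name = "var1") {
  g <- nc_grid(0, 0, 60, 1, length(values))
  climate_stack(g, stats::setNames(
    list(matrix(values, 1, length(values))), name))
}

# A small smooth 2-variable landscape (n x m cells) for fitting tests.
toy_stack <- function(n_rows = 10, n_cols = 10, seed = 1) {
  g <- nc_grid(0, 0, 60, n_rows, n_cols)
  set.seed(seed)
  lat <- matrix(row_center_lat(g), n_rows, n_cols)
  lon <- matrix(g$west + (seq_len(n_cols) - 0.5) * g$res_deg,
                n_rows, n_cols, byrow = TRUE)
  climate_stack(g, list(
    var1 = 20 - lat + 0.5 * sin(lon) + matrix(rnorm(n_rows * n_cols, 0, .1),
                                              n_rows),
    var2 = lon + 0.3 * lat + matrix(rnorm(n_rows * n_cols, 0, .1), n_rows)))
}

# Brute-force Fisher-Jenks: enumerate every split of the sorted values into
# k contiguous nonempty classes and return the minimal within-class SSD.
jenks_brute_force <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  ssd <- function(x) sum((x - mean(x))^2)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, j], n)
    tot <- sum(vapply(seq_len(k), function(i)
      ssd(v[(bounds[i] + 1):bounds[i + 1]]), numeric(1)))
    if (tot < best) best <- tot
  }
  best
}

# Jenks objective of a fitted break set, recomputed from scratch on values.
jenks_objective <- function(values, breaks) {
  v <- sort(values)
  cls <- rowSums(outer(v, breaks, `>=`))
  sum(vapply(split(v, cls), function(x) sum((x - mean(x))^2), numeric(1)))
}

# Brute-force maximizer of the penalized maxent objective by coarse-to-fine
# grid search over lambda (feasible for <= 3 features). Returns the best
# objective value found.
maxent_brute_force <- function(zp, zb, beta, half_width = 8, rounds = 4,
                               pts = 11) {
  d <- ncol(zb)
  obj <- function(lambda) {
    eta <- drop(zb %*% lambda)
    m <- max(eta)
    mean(drop(zp %*% lambda)) - (m + log(sum(exp(eta - m)))) -
      sum(beta * abs(lambda))
  }
  center <- numeric(d)
  width <- half_width
  best <- obj(center)
  for (r in seq_len(rounds)) {
    axes <- lapply(seq_len(d), function(j)
      seq(center[j] - width, center[j] + width, length.out = pts))
    grid <- as.matrix(do.call(expand.grid, axes))
    vals <- apply(grid, 1, obj)
    i <- which.max(vals)
    center <- grid[i, ]
    best <- vals[i]
    width <- width * 2.2 / (pts - 1)   # keep neighbors of the best point
  }
  best
}

# Writes a small occurrence CSV fixture and returns its path.
write_occ_fixture <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}
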