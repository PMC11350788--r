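#' Pearson correlation matrix of stack layers
#'
#' Computed over a seeded random sample of unmasked cells (all cells when the
#' landscape is smaller than `sample_cells`). A constant layer has no defined
#' correlation; it is reported as 0 against every other layer, with a warning,
#' so that screening can still flag it downstream.
#'
#' @param stack A `climate_stack` with at least two layers.
#' @param sample_cells Number of cells to sample (default 10000).
#' @param seed Integer seed for the cell sample.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(stack, sample_cells = 10000, seed = 1) {
  stopifnot(length(stack$layers) >= 2, sample_cells >= 2)
  cells <- unmasked_cells(stack)
  if (length(cells) > sample_cells) {
    set.seed(seed)
    cells <- sort(sample(cells, sample_cells))
  }
  z <- stack_values(stack, cells)
  sds <- apply(z, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const))
    warning("constant layer(s) treated as correlation 0: ",
            paste(colnames(z)[const], collapse = ", "))
  r <- suppressWarnings(stats::cor(z))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r
}

#' Variance inflation factor of one column
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from the ordinary least squares
#' regression of column `j` on all other columns. Perfect collinearity yields
#' `Inf`.
#'
#' @param values_matrix Numeric matrix, columns = variables (>= 2), rows >
#'   columns.
#' @param column_j Column index or name.
#' @return The VIF (>= 1, possibly `Inf`).
#' @export
vif <- function(values_matrix, column_j) {
  z <- as.matrix(values_matrix)
  stopifnot(ncol(z) >= 2, nrow(z) >= ncol(z) + 1)
  if (is.character(column_j)) column_j <- match(column_j, colnames(z))
  y <- z[, column_j]
  x <- z[, -column_j, drop = FALSE]
  fit <- stats::lm.fit(cbind(1, x), y)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(Inf)  # constant column: undefined, flag as extreme
  r2 <- 1 - sum(fit$residuals^2) / ss_tot
  if (r2 >= 1 - 1e-12) return(Inf)
  1 / (1 - r2)
}

vif_all <- function(z) {
  stats::setNames(vapply(seq_len(ncol(z)), function(j) vif(z, j), numeric(1)),
                  colnames(z))
}

#' Screen stack variables by correlation then variance inflation
#'
#' Two-stage collinearity screening. Stage 1: while any pair of retained
#' layers has `|r| > r_max`, take the worst pair and drop the member with the
#' larger mean absolute correlation against all other retained layers (a
#' deterministic, order-independent tie-break). Stage 2: iteratively drop the
#' layer with the largest VIF, recomputing after each drop, until all VIFs
#' are at most `vif_max`. Both stages are computed on one seeded cell sample
#' of the supplied (current-scenario) stack; the retained set is then fixed
#' for every projection.
#'
#' @param stack A `climate_stack`.
#' @param r_max Absolute pairwise correlation cutoff, in (0, 1) (default 0.8).
#' @param vif_max VIF cutoff, > 1 (default 10).
#' @param sample_cells,seed Passed to the cell sampler.
#' @return An object of class `variable_selection`: `retained` (names),
#'   `dropped` (data frame of name / stage / statistic), and the full initial
#'   correlation matrix.
#' @export
select_variables <- function(stack, r_max = 0.8, vif_max = 10,
                             sample_cells = 10000, seed = 1) {
  stopifnot(r_max > 0, r_max < 1, vif_max > 1)
  cells <- unmasked_cells(stack)
  if (length(cells) > sample_cells) {
    set.seed(seed)
    cells <- sort(sample(cells, sample_cells))
  }
  z <- stack_values(stack, cells)
  full_r <- suppressWarnings(stats::cor(z)); full_r[!is.finite(full_r)] <- 0
  diag(full_r) <- 1
  keep <- colnames(z)
  dropped <- data.frame(name = character(0), reason = character(0),
                        statistic = numeric(0), stringsAsFactors = FALSE)

  # stage 1: pairwise correlation
  repeat {
    if (length(keep) < 2) break
    r <- abs(full_r[keep, keep, drop = FALSE]); diag(r) <- 0
    worst <- max(r)
    if (worst <= r_max) break
    ij <- which(r == worst, arr.ind = TRUE)[1, ]
    pair <- keep[ij]
    mean_abs <- rowMeans(abs(full_r[pair, keep, drop = FALSE])) # includes self=1, same for both
    drop_v <- pair[which.max(mean_abs)]
    dropped <- rbind(dropped, data.frame(name = drop_v, reason = "correlation",
                                         statistic = worst,
                                         stringsAsFactors = FALSE))
    keep <- setdiff(keep, drop_v)
  }

  # stage 2: iterative VIF elimination
  repeat {
    if (length(keep) < 2) break
    v <- vif_all(z[, keep, drop = FALSE])
    if (max(v) <= vif_max) break
    drop_v <- names(v)[which.max(v)]
    dropped <- rbind(dropped, data.frame(name = drop_v, reason = "vif",
                                         statistic = unname(max(v)),
                                         stringsAsFactors = FALSE))
    keep <- setdiff(keep, drop_v)
  }

  if (length(keep) < 2)
    stop("fewer than 2 variables survive screening; relax r_max/vif_max")
  structure(list(retained = keep, dropped = dropped, correlation = full_r,
                 r_max = r_max, vif_max = vif_max,
                 n_cells = length(cells)),
            class = "variable_selection")
}

#' @export
print.variable_selection <- function(x, ...) {
  cat(sprintf("<variable_selection> retained %d of %d variable(s)\n",
              length(x$retained), length(x$retained) + nrow(x$dropped)))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped))
    for (i in seq_len(nrow(x$dropped)))
      cat(sprintf("  dropped %s (%s = %.3g)\n", x$dropped$name[i],
                  x$dropped$reason[i], x$dropped$statistic[i]))
  invisible(x)
}

#' Write a variable-selection report
#' @param sel A `variable_selection`.
#' @param json_path JSON report path.
#' @param cor_csv_path Optional CSV path for the correlation matrix.
#' @export
write_selection <- function(sel, json_path, cor_csv_path = NULL) {
  jsonlite::write_json(
    list(retained = sel$retained,
         dropped = sel$dropped,
         r_max = sel$r_max, vif_max = sel$vif_max, n_cells = sel$n_cells),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(cor_csv_path))
    utils::write.csv(sel$correlation, cor_csv_path)
  invisible(json_path)
}
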