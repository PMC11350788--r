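#' Build a feature map for maximum-entropy fitting
#'
#' Maps raw climate values to model features normalized to `[0, 1]` over the
#' training landscape: for each variable a linear feature
#' `z = (v - min) / (max - min)` and (by default) its square, plus optional
#' pairwise products. Normalization bounds are the per-variable min/max over
#' the unmasked cells of the training stack; on projection, features are
#' clamped back into these bounds unless disabled.
#'
#' @param stack Training `climate_stack`.
#' @param variables Layer names to use (default: all).
#' @param quadratic Include squared features (default `TRUE`).
#' @param products Include pairwise product features (default `FALSE`).
#' @return An object of class `feature_map`.
#' @export
feature_map <- function(stack, variables = names(stack$layers),
                        quadratic = TRUE, products = FALSE) {
  cells <- unmasked_cells(stack)
  z <- stack_values(stack, cells, variables)
  lo <- apply(z, 2, min); hi <- apply(z, 2, max)
  feats <- paste0(variables, ":lin")
  if (quadratic) feats <- c(feats, paste0(variables, ":sq"))
  if (products && length(variables) > 1) {
    cmb <- utils::combn(variables, 2)
    feats <- c(feats, paste0(cmb[1, ], "*", cmb[2, ], ":prod"))
  }
  structure(list(variables = variables, lo = lo, hi = hi,
                 quadratic = quadratic, products = products,
                 feature_names = feats),
            class = "feature_map")
}

#' Evaluate features at cells
#' @param fm A `feature_map`.
#' @param stack A `climate_stack` holding all of `fm$variables`.
#' @param cells Linear cell indices.
#' @param clamp Clamp normalized values into `[0, 1]` (training bounds).
#' @return Numeric matrix, one row per cell, one column per feature.
#' @export
features_at <- function(fm, stack, cells, clamp = TRUE) {
  v <- stack_values(stack, cells, fm$variables)
  rng <- fm$hi - fm$lo
  rng[rng == 0] <- 1  # constant variable: feature fixed at 0
  z <- sweep(sweep(v, 2, fm$lo), 2, rng, "/")
  if (clamp) z <- pmin(pmax(z, 0), 1)
  out <- z
  if (fm$quadratic) out <- cbind(out, z^2)
  if (fm$products && length(fm$variables) > 1) {
    cmb <- utils::combn(seq_along(fm$variables), 2)
    out <- cbind(out, z[, cmb[1, ], drop = FALSE] * z[, cmb[2, ], drop = FALSE])
  }
  colnames(out) <- fm$feature_names
  out
}

#' Sample background cells
#'
#' Uniform sample without replacement of unmasked cells, capped at
#' `max_points` (all cells when the landscape is smaller than the cap).
#'
#' @param stack A `climate_stack`.
#' @param max_points Background cap (default 100000).
#' @param seed Integer seed.
#' @return Sorted integer vector of cell indices.
#' @export
sample_background <- function(stack, max_points = 1e5, seed = 1) {
  stopifnot(max_points >= 1)
  cells <- unmasked_cells(stack)
  if (!length(cells)) stop("no unmasked cells to sample background from")
  if (length(cells) <= max_points) return(cells)
  set.seed(seed)
  sort(sample(cells, max_points))
}

logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

# penalized log-likelihood: mean presence log-density minus L1 penalty
maxent_objective <- function(lambda, zp, zb, beta) {
  eta <- drop(zb %*% lambda)
  mean(drop(zp %*% lambda)) - logsumexp(eta) - sum(beta * abs(lambda))
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Solve the proximal Newton subproblem
#   max_d  g.d - d'Hd/2 - sum_j beta_j |lambda_j + d_j|
# by cyclic coordinate descent with exact soft-threshold updates.
prox_newton_direction <- function(lambda, g, H, beta,
                                  sweeps = 100, tol = 1e-10) {
  d <- numeric(length(lambda))
  h <- diag(H)
  for (s in seq_len(sweeps)) {
    delta_max <- 0
    for (j in seq_along(d)) {
      gj <- g[j] - sum(H[j, ] * d) + h[j] * d[j]   # partial resid. gradient
      new_x <- soft_threshold(lambda[j] + gj / h[j], beta[j] / h[j])
      new_dj <- new_x - lambda[j]
      delta_max <- max(delta_max, abs(new_dj - d[j]))
      d[j] <- new_dj
    }
    if (delta_max < tol * max(1, max(abs(d)))) break
  }
  d
}

#' Fit a presence-background maximum-entropy model
#'
#' Estimates the Gibbs distribution `q(x) = exp(lambda . z(x)) / Z` over the
#' background landscape that maximizes the L1-penalized presence
#' log-likelihood
#' `(1/|P|) sum_P lambda . z(x) - log Z - sum_j beta_j |lambda_j|`.
#' The objective is concave and is maximized by a proximal Newton method:
#' each iteration builds the local quadratic model from the gradient
#' `mean_P z - E_q z` and the Hessian `-Cov_q(z)`, solves the L1-penalized
#' quadratic subproblem by cyclic coordinate soft-thresholding, and
#' backtracks on the true objective. Second-order steps matter here: narrow
#' niches on a wide climate range need coefficients orders of magnitude
#' larger than the feature scale, which first-order updates cannot reach.
#' At an interior optimum the fitted feature expectations under `q` match the
#' presence means within the regularization slack:
#' `|E_q z_j - mean_P z_j| <= beta_j`.
#'
#' @param presence_cells Cell indices of presences (>= 1).
#' @param background_cells Cell indices of the background sample (>= 2).
#' @param stack Training `climate_stack`.
#' @param fm A `feature_map` (default: linear + quadratic on all layers).
#' @param beta_scale Global regularization knob:
#'   `beta_j = beta_scale * sd_j / sqrt(m)` with `sd_j` the feature's
#'   standard deviation over the background and `m` the number of presences
#'   (default 0.05). The `1/sqrt(m)` factor scales the allowed slack on each
#'   constrained feature mean like the standard error of that mean, so the
#'   model tightens as evidence accumulates. Ignored when `beta` is given.
#' @param beta Optional explicit per-feature penalty vector (recycled).
#' @param tol Convergence tolerance on the relative objective change
#'   (default 1e-5).
#' @param max_iter Iteration cap (default 500).
#' @return An object of class `maxent_model` with elements `lambda` (named,
#'   full feature length; zero for dropped features), `log_z`, `entropy`,
#'   `beta`, `feature_map`, `background_cells`, `objective`, `converged`,
#'   `iterations`.
#' @export
fit_maxent <- function(presence_cells, background_cells, stack,
                       fm = feature_map(stack), beta_scale = 0.05,
                       beta = NULL, tol = 1e-5, max_iter = 500) {
  stopifnot(length(presence_cells) >= 1, length(background_cells) >= 2)
  zp_full <- features_at(fm, stack, presence_cells)
  zb_full <- features_at(fm, stack, background_cells)
  n_feat <- ncol(zb_full)
  sds <- apply(zb_full, 2, stats::sd)
  active <- which(sds > 0)
  if (!length(active))
    warning("all features have zero variance over the background; ",
            "model is uniform")
  else if (length(active) < n_feat)
    warning("dropping zero-variance feature(s): ",
            paste(colnames(zb_full)[-active], collapse = ", "))
  zp <- zp_full[, active, drop = FALSE]
  zb <- zb_full[, active, drop = FALSE]
  if (is.null(beta)) beta <- beta_scale * sds[active] / sqrt(nrow(zp))
  else beta <- rep_len(beta, length(active))

  lambda <- numeric(length(active))
  p_mean <- if (length(active)) colMeans(zp) else numeric(0)
  obj <- maxent_objective(lambda, zp, zb, beta)
  converged <- FALSE
  it <- 0L
  while (it < max_iter && length(active)) {
    it <- it + 1L
    eta <- drop(zb %*% lambda)
    lz <- logsumexp(eta)
    q <- exp(eta - lz)
    mu_q <- drop(crossprod(zb, q))
    grad <- p_mean - mu_q
    zc <- sweep(zb, 2, mu_q)
    hess <- crossprod(zc, zc * q)               # Cov_q(z)
    diag(hess) <- diag(hess) + 1e-9 * max(diag(hess), 1)
    d <- prox_newton_direction(lambda, grad, hess, beta)
    if (max(abs(d)) < 1e-14) { converged <- TRUE; break }
    # backtracking on the true objective along the Newton direction
    t_step <- 1
    repeat {
      cand <- lambda + t_step * d
      new_obj <- maxent_objective(cand, zp, zb, beta)
      if (new_obj > obj + 1e-12 || t_step < 1e-10) break
      t_step <- t_step / 2
    }
    if (new_obj <= obj + 1e-12) break           # no ascent possible
    rel <- (new_obj - obj) / max(1, abs(obj))
    lambda <- cand
    obj <- new_obj
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!length(active)) converged <- TRUE

  lambda_full <- stats::setNames(numeric(n_feat), colnames(zb_full))
  lambda_full[active] <- lambda
  eta_b <- drop(zb_full %*% lambda_full)
  log_z <- logsumexp(eta_b)
  q <- exp(eta_b - log_z)
  entropy <- log_z - sum(lambda_full * drop(crossprod(zb_full, q)))
  structure(list(lambda = lambda_full, log_z = log_z, entropy = entropy,
                 beta = beta, feature_map = fm,
                 background_cells = background_cells,
                 objective = obj, converged = converged, iterations = it),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d feature(s), H = %.4g, %s after %d iteration(s)\n",
              length(x$lambda), x$entropy,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(round(x$lambda, 4))
  invisible(x)
}

#' Predict logistic suitability over a stack
#'
#' Computes the raw Gibbs density `q(x)` from the fitted coefficients and the
#' training-landscape normalizer, then the logistic output
#' `p(x) = e^H q(x) / (1 + e^H q(x))` with `H` the entropy of the fitted
#' distribution; `p` lies in `[0, 1]` and is 0.5 at cells of typical
#' (entropy-level) suitability. Features are clamped to training bounds when
#' projecting onto new climates.
#'
#' @param model A `maxent_model`.
#' @param stack Target `climate_stack` (current or future scenario).
#' @param species Species id recorded on the map.
#' @param clamp Clamp projected features to training bounds (default `TRUE`).
#' @return A `suitability_map`: grid, matrix of `p` values (NA on mask),
#'   species and scenario/horizon labels.
#' @export
predict_logistic <- function(model, stack, species = NA_character_,
                             clamp = TRUE) {
  cells <- unmasked_cells(stack)
  z <- features_at(model$feature_map, stack, cells, clamp = clamp)
  log_q <- drop(z %*% model$lambda) - model$log_z
  p <- stats::plogis(model$entropy + log_q)
  vals <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  vals[cells] <- p
  structure(list(grid = stack$grid, values = vals, species = species,
                 scenario = stack$scenario, horizon = stack$horizon,
                 n_replicates = 1L),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf(
    "<suitability_map> %s [%s/%s]: %d cells, p in [%.3g, %.3g], mean %.3g\n",
    x$species, x$scenario, x$horizon, length(v), min(v), max(v), mean(v)))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a presence score exceeds a background score, ties counted
#' one half — the rank-sum estimator of the AUC.
#'
#' @param presence_scores,background_scores Nonempty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  stopifnot(length(presence_scores) >= 1, length(background_scores) >= 1)
  np <- length(presence_scores); nb <- length(background_scores)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Training gain of a fitted model
#'
#' Mean presence log-density improvement over the uniform background
#' distribution: `mean_P log q(x) + log n_background`. Zero for an
#' uninformative model.
#'
#' @param model A `maxent_model`.
#' @param presence_cells Presence cell indices.
#' @param stack Training stack.
#' @return The gain (nats).
#' @export
maxent_gain <- function(model, presence_cells, stack) {
  z <- features_at(model$feature_map, stack, presence_cells)
  mean(drop(z %*% model$lambda)) - model$log_z +
    log(length(model$background_cells))
}

#' Replicated fit with train/validation splits
#'
#' Repeats the split / background sample / fit / predict cycle with
#' per-replicate seeds derived from `seed`, and averages the logistic maps
#' cell-wise. Per-replicate train/test AUCs are kept alongside their means.
#'
#' @param presence_cells Presence cell indices (>= 2 for a split).
#' @param stack Training `climate_stack`.
#' @param n_replicates Number of replicates (default 7).
#' @param seed Master seed for this species.
#' @param train_fraction Training fraction for each split (default 0.75).
#' @param background_cap Background sample cap (default 100000).
#' @param species Species id for the map.
#' @param ... Passed to [fit_maxent()] (e.g. `fm`, `beta_scale`, `tol`).
#' @return An object of class `replicate_fit`: `map` (mean
#'   `suitability_map`), `models` (list), `metrics` (per-replicate data
#'   frame), `mean_auc_train`, `mean_auc_test`.
#' @export
fit_replicates <- function(presence_cells, stack, n_replicates = 7, seed = 1,
                           train_fraction = 0.75, background_cap = 1e5,
                           species = NA_character_, ...) {
  stopifnot(n_replicates >= 1, length(presence_cells) >= 2)
  models <- vector("list", n_replicates)
  maps <- vector("list", n_replicates)
  metrics <- data.frame()
  for (i in seq_len(n_replicates)) {
    rep_seed <- (seed + 7919L * i) %% .Machine$integer.max
    sp <- split_train_test(length(presence_cells), train_fraction, rep_seed)
    train_cells <- presence_cells[sp$train]
    test_cells <- presence_cells[sp$test]
    bg <- sample_background(stack, background_cap, rep_seed)
    m <- tryCatch(
      fit_maxent(train_cells, bg, stack, ...),
      error = function(e) stop("replicate ", i, " failed: ",
                               conditionMessage(e), call. = FALSE))
    sm <- predict_logistic(m, stack, species = species)
    bg_scores <- sm$values[bg]
    metrics <- rbind(metrics, data.frame(
      replicate = i, seed = rep_seed,
      auc_train = auc(sm$values[train_cells], bg_scores),
      auc_test = auc(sm$values[test_cells], bg_scores),
      n_train = length(train_cells), n_test = length(test_cells),
      n_background = length(bg), gain = maxent_gain(m, train_cells, stack)))
    models[[i]] <- m
    maps[[i]] <- sm$values
  }
  mean_vals <- Reduce(`+`, maps) / n_replicates
  map <- structure(list(grid = stack$grid, values = mean_vals,
                        species = species, scenario = stack$scenario,
                        horizon = stack$horizon,
                        n_replicates = as.integer(n_replicates)),
                   class = "suitability_map")
  structure(list(map = map, models = models, metrics = metrics,
                 mean_auc_train = mean(metrics$auc_train),
                 mean_auc_test = mean(metrics$auc_test)),
            class = "replicate_fit")
}

#' @export
print.replicate_fit <- function(x, ...) {
  cat(sprintf("<replicate_fit> %d replicate(s): AUC train %.3f, test %.3f\n",
              nrow(x$metrics), x$mean_auc_train, x$mean_auc_test))
  invisible(x)
}

#' Project a replicated fit onto another climate stack
#'
#' Averages the per-replicate logistic predictions on the target stack,
#' mirroring the cell-wise averaging used on the training stack.
#'
#' @param rep_fit A `replicate_fit`.
#' @param stack Target `climate_stack`.
#' @return A `suitability_map` on the target scenario/horizon.
#' @export
project_replicates <- function(rep_fit, stack) {
  maps <- lapply(rep_fit$models, function(m)
    predict_logistic(m, stack, species = rep_fit$map$species)$values)
  vals <- Reduce(`+`, maps) / length(maps)
  structure(list(grid = stack$grid, values = vals,
                 species = rep_fit$map$species, scenario = stack$scenario,
                 horizon = stack$horizon,
                 n_replicates = length(rep_fit$models)),
            class = "suitability_map")
}

#' Jackknife variable-importance report
#'
#' Leave-one-variable-out and only-one-variable training gains, the standard
#' diagnostic for how much signal each predictor carries. Purely a report; it
#' never alters the fitted model.
#'
#' @param presence_cells Presence cell indices.
#' @param background_cells Background cell indices.
#' @param stack Training stack.
#' @param variables Variables to assess (default: all layers).
#' @param ... Passed to [fit_maxent()].
#' @return Data frame: variable, `gain_without`, `gain_only`, plus the
#'   full-model gain in attribute `"gain_full"`.
#' @export
jackknife_gains <- function(presence_cells, background_cells, stack,
                            variables = names(stack$layers), ...) {
  fit_gain <- function(vars) {
    fm <- feature_map(stack, vars)
    m <- fit_maxent(presence_cells, background_cells, stack, fm = fm, ...)
    maxent_gain(m, presence_cells, stack)
  }
  out <- data.frame(variable = variables,
                    gain_without = NA_real_, gain_only = NA_real_)
  for (i in seq_along(variables)) {
    if (length(variables) > 1)
      out$gain_without[i] <- fit_gain(setdiff(variables, variables[i]))
    out$gain_only[i] <- fit_gain(variables[i])
  }
  attr(out, "gain_full") <- fit_gain(variables)
  out
}
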