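#' Run configuration
#'
#' Bundles every tunable of the assessment pipeline with its default:
#' species below `min_records` records go to the data-poor path; splits are
#' 75/25; the background sample is capped at 100,000 cells; predictors are
#' screened at |r| > 0.8 then VIF > 10; suitability is cut into 4 classes;
#' 7 replicate models are averaged.
#'
#' @param min_records Minimum records for the model path (default 4).
#' @param train_fraction Training fraction per replicate (default 0.75).
#' @param background_cap Background sample cap (default 100000).
#' @param r_max Pairwise correlation cutoff (default 0.8).
#' @param vif_max VIF cutoff (default 10).
#' @param n_classes Habitability classes (default 4).
#' @param n_replicates Replicates averaged per species (default 7).
#' @param beta_scale Global regularization knob (default 0.05).
#' @param sample_cells Cell subsample for screening and break fitting.
#' @param baseline_default Baseline category for data-poor elevation.
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(min_records = 4, train_fraction = 0.75,
                       background_cap = 1e5, r_max = 0.8, vif_max = 10,
                       n_classes = 4, n_replicates = 7, beta_scale = 0.05,
                       sample_cells = 10000, baseline_default = "LC",
                       seed = 1) {
  stopifnot(min_records >= 1, train_fraction > 0, train_fraction < 1,
            background_cap >= 1, r_max > 0, r_max < 1, vif_max > 1,
            n_classes >= 2, n_replicates >= 1, beta_scale >= 0,
            baseline_default %in% IUCN_LEVELS)
  structure(list(min_records = min_records, train_fraction = train_fraction,
                 background_cap = background_cap, r_max = r_max,
                 vif_max = vif_max, n_classes = n_classes,
                 n_replicates = n_replicates, beta_scale = beta_scale,
                 sample_cells = sample_cells,
                 baseline_default = baseline_default,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#' @param config A `run_config`.
#' @param path File path.
#' @return `read_config` returns a `run_config` equal to the written one.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Stable per-species seed
#'
#' Derives a sub-seed from the master seed and the species id with a
#' polynomial rolling hash, so adding or removing a species never perturbs
#' any other species' random draws.
#'
#' @param master_seed Integer master seed.
#' @param species_id Species id string.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
species_seed <- function(master_seed, species_id) {
  h <- as.numeric(master_seed) %% 2147483647
  for (code in utf8ToInt(species_id))
    h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

stack_subset <- function(stack, variables) {
  climate_stack(stack$grid, stack$layers[variables], stack$scenario,
                stack$horizon)
}

#' Build a synthetic study with known truth
#'
#' Emulates the real study's inputs at desk scale: a 90 x 180 global grid at
#' 2 degrees with three climate layers (the first temperature-like), four
#' future stacks (two emissions pathways x two horizons, as additive warming
#' deltas of 1.8 / 2.4 degC for the moderate pathway and 2.4 / 3.8 degC for
#' the severe one, with mild drying in the second layer), and virtual species
#' with Gaussian niches. Model species carry 200 presence records sampled
#' proportional to suitability; data-poor species carry 1-3 records.
#'
#' Niche centers sit on the cool flank of the temperature field (centers
#' -28 to 0 degC, niche sd 4-5 degC) so that warming truncates ranges
#' against the polar climate margin — the trailing-edge geometry that drives
#' losses in the real system — with the center temperature dialing the true
#' loss fraction. The second-variable niche is broad (sd 15-30) and centered
#' on conditions inside the species' thermal band, so that variable refines
#' but does not dominate the range.
#'
#' @param n_species Number of model species (default 20).
#' @param n_data_poor Number of data-poor species (default 3: one each with
#'   1, 2, 3 records).
#' @param seed Master seed.
#' @param grid Study grid (default 90 x 180 at 2 degrees).
#' @param avoid_thresholds If `TRUE`, redraw species whose true loss under
#'   `eval_scenario` falls within 0.05 of a category threshold, so recovery
#'   can be scored unambiguously.
#' @param eval_scenario Scenario label used for the threshold-avoidance
#'   screen (default `"SSP5-8.5_2070s"`).
#' @return List: `current` (stack), `scenarios` (named list of stacks),
#'   `species` (list of `virtual_species`), `occurrences` (an
#'   `occurrence_set`), `baseline` (named category vector, all `"LC"`),
#'   `true_loss` (species x scenario matrix).
#' @export
synthesize_study <- function(n_species = 20, n_data_poor = 3, seed = 1,
                             grid = nc_grid(-180, -90, 120, 90, 180),
                             avoid_thresholds = TRUE,
                             eval_scenario = "SSP5-8.5_2070s") {
  current <- generate_climate(grid, n_variables = 3, seed = seed)
  deltas <- list(
    scenario_delta(c(var1 = 1.8, var2 = -2), "SSP2-4.5", "2050s"),
    scenario_delta(c(var1 = 2.4, var2 = -3), "SSP2-4.5", "2070s"),
    scenario_delta(c(var1 = 2.4, var2 = -4), "SSP5-8.5", "2050s"),
    scenario_delta(c(var1 = 3.8, var2 = -6), "SSP5-8.5", "2070s"))
  scenarios <- list()
  for (d in deltas)
    scenarios[[paste(d$label, d$horizon, sep = "_")]] <-
      apply_delta(current, d)

  v1m <- current$layers$var1
  v2m <- current$layers$var2
  v2 <- v2m[unmasked_cells(current)]

  species <- list()
  records <- list()
  set.seed(species_seed(seed, "species-roster"))
  attempts <- 0
  while (length(species) < n_species && attempts < 100 * n_species) {
    attempts <- attempts + 1
    id <- sprintf("vsp%02d", length(species) + 1)
    t_c <- stats::runif(1, -28, 0)           # cool-flank thermal center
    sd_t <- stats::runif(1, 4, 5)
    band <- !is.na(v1m) & abs(v1m - t_c) < 1.2 * sd_t
    if (sum(band) < 30) next
    mu <- c(var1 = t_c, var2 = mean(v2m[band]) + stats::rnorm(1, 0, 3))
    sigma <- diag(c(sd_t^2, stats::runif(1, 15, 30)^2))
    vs <- make_virtual_species(current, mu, sigma, s_star = 0.05, id = id,
                               scenario_stacks = scenarios)
    if (sum(vs$true_range$current) < 60) next  # too small to model reliably
    if (avoid_thresholds) {
      L <- true_loss_fraction(vs, eval_scenario)
      if (min(abs(L - c(0, 0.1, 0.3, 0.5, 0.8, 1))) <= 0.05) next
    }
    species[[id]] <- vs
    records[[id]] <- sample_presences(vs, n = 200,
                                      seed = species_seed(seed, id))
  }
  if (length(species) < n_species)
    stop("could not realize ", n_species, " species under the study design")

  # data-poor species: tight mid-latitude niches emitting 1-3 records
  for (k in seq_len(n_data_poor)) {
    id <- sprintf("dpsp%02d", k)
    t_c <- stats::runif(1, 5, 20)
    band <- !is.na(v1m) & abs(v1m - t_c) < 2.4
    mu <- c(var1 = t_c, var2 = mean(v2m[band]))
    vs <- make_virtual_species(current, mu, diag(c(2^2, 20^2)), 0.05, id,
                               scenario_stacks = scenarios,
                               n_records = ((k - 1) %% 3) + 1)
    species[[id]] <- vs
    records[[id]] <- sample_presences(vs, n = vs$n_records,
                                      seed = species_seed(seed, id))
  }

  occ <- occurrence_set(do.call(rbind, c(records, list(make.row.names = FALSE))))
  occ <- log_step(occ, "synthesize", n_species = length(species))
  true_loss <- sapply(names(scenarios), function(lbl)
    sapply(species, true_loss_fraction, scenario_label = lbl))
  list(current = current, scenarios = scenarios, species = species,
       occurrences = occ,
       baseline = stats::setNames(rep("LC", length(species)), names(species)),
       true_loss = true_loss)
}

#' Run the full assessment pipeline
#'
#' Per species: screen predictors (once, on the current stack), fit the
#' replicated presence-background model, binarize with natural breaks fitted
#' on the current suitability, project to every scenario x horizon with the
#' same breaks, and assess the threat category from the projected range-loss
#' fraction. Species below the record threshold (or whose modeled current
#' range is empty) are assessed on the data-poor geometry path; their status
#' is held constant across horizons within each scenario. Failures are
#' isolated per species and logged.
#'
#' @param occurrences An `occurrence_set`.
#' @param current Current-scenario `climate_stack`.
#' @param scenarios Named list of future `climate_stack`s; names should be
#'   `"<scenario>_<horizon>"` or carry the labels on the stacks.
#' @param config A `run_config`.
#' @param baseline Named vector of current IUCN categories per species
#'   (used for data-poor elevation and transition tables); species missing
#'   from it use `config$baseline_default`.
#' @return A `run_report`: `assessments` (data frame), `metrics` (per-species
#'   replicate AUC summary), `selection`, `breaks`, `ranges` (per species:
#'   current + per-scenario `binary_range`s), `transitions`, `richness`,
#'   `failures`, `config`.
#' @export
run_assessment <- function(occurrences, current, scenarios, config = run_config(),
                           baseline = NULL) {
  stopifnot(inherits(occurrences, "occurrence_set"),
            inherits(current, "climate_stack"))
  base_cat <- function(sp) {
    b <- if (!is.null(baseline) && sp %in% names(baseline)) baseline[[sp]]
         else config$baseline_default
    if (!b %in% IUCN_LEVELS) config$baseline_default else b
  }

  occ <- filter_min_records(occurrences, config$min_records)
  model_ids <- sort(unique(occ$records$species))
  poor_ids <- sort(unique(occ$data_poor$species))
  if (!length(model_ids) && !length(poor_ids))
    stop("no species passes the filters; see the occurrence filter log")

  selection <- select_variables(current, config$r_max, config$vif_max,
                                config$sample_cells, config$seed)
  cur_sub <- stack_subset(current, selection$retained)
  scen_sub <- lapply(scenarios, stack_subset, variables = selection$retained)

  occ_cells <- dedupe_to_cells(occ, current$grid)

  assessments <- list(); metrics <- list(); breaks <- list()
  ranges <- list(); failures <- list()

  for (sp in model_ids) {
    res <- tryCatch({
      rec <- occ_cells$records[occ_cells$records$species == sp, , drop = FALSE]
      cells <- cell_index(current$grid, rec$lon, rec$lat)
      cells <- unique(cells[!is.na(cells) &
                              !is.na(current$layers[[1]][cells])])
      if (length(cells) < 2)
        stop("fewer than 2 usable cells after deduplication")
      sp_seed <- species_seed(config$seed, sp)
      fit <- fit_replicates(cells, cur_sub,
                            n_replicates = config$n_replicates,
                            seed = sp_seed,
                            train_fraction = config$train_fraction,
                            background_cap = config$background_cap,
                            species = sp, beta_scale = config$beta_scale)
      bs <- jenks_breaks(fit$map$values, config$n_classes,
                         max_sample = config$sample_cells, seed = sp_seed,
                         source = "current")
      cur_range <- to_binary_range(classify_suitability(fit$map, bs))
      sp_ranges <- list(current = cur_range)
      sp_assess <- list()
      for (lbl in names(scen_sub)) {
        proj <- project_replicates(fit, scen_sub[[lbl]])
        fut_range <- to_binary_range(classify_suitability(proj, bs))
        sp_ranges[[lbl]] <- fut_range
        sp_assess[[lbl]] <- assess_species(
          sp, scen_sub[[lbl]]$scenario, scen_sub[[lbl]]$horizon,
          current_range = cur_range, future_range = fut_range,
          records = occ$records[occ$records$species == sp, , drop = FALSE],
          baseline = base_cat(sp))
      }
      list(assess = do.call(rbind, sp_assess),
           metric = data.frame(species = sp,
                               auc_train = fit$mean_auc_train,
                               auc_test = fit$mean_auc_test,
                               n_cells = length(cells),
                               n_replicates = config$n_replicates),
           breaks = bs, ranges = sp_ranges)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[sp]] <- conditionMessage(res)
      next
    }
    assessments[[sp]] <- res$assess
    metrics[[sp]] <- res$metric
    breaks[[sp]] <- res$breaks
    ranges[[sp]] <- res$ranges
  }

  # data-poor path: geometry-based, constant across horizons per scenario
  scen_labels <- unique(do.call(rbind, lapply(scen_sub, function(s)
    data.frame(scenario = s$scenario, horizon = s$horizon))))
  for (sp in poor_ids) {
    rec <- occ$data_poor[occ$data_poor$species == sp, , drop = FALSE]
    rows <- list()
    for (sc in unique(scen_labels$scenario)) {
      horizons <- sort(scen_labels$horizon[scen_labels$scenario == sc])
      first <- assess_species(sp, sc, horizons[1], records = rec,
                              baseline = base_cat(sp))
      rows[[sc]] <- first
      for (h in horizons[-1]) {          # status held constant across horizons
        cp <- first; cp$horizon <- h
        rows[[paste(sc, h)]] <- cp
      }
    }
    assessments[[sp]] <- do.call(rbind, rows)
  }

  assessments <- do.call(rbind, c(assessments, list(make.row.names = FALSE)))
  metrics <- if (length(metrics))
    do.call(rbind, c(metrics, list(make.row.names = FALSE))) else
    data.frame()

  transitions <- list(); richness <- list()
  if (length(ranges)) {
    cur_r <- lapply(ranges, `[[`, "current")
    richness$current <- richness_map(cur_r)
  }
  all_base <- stats::setNames(
    vapply(unique(assessments$species), base_cat, character(1)),
    unique(assessments$species))
  for (lbl in names(scen_sub)) {
    sc <- scen_sub[[lbl]]$scenario; h <- scen_sub[[lbl]]$horizon
    sub <- assessments[assessments$scenario == sc & assessments$horizon == h, ]
    transitions[[lbl]] <- transition_table(sub, all_base)
    if (length(ranges))
      richness[[lbl]] <- richness_map(lapply(ranges, `[[`, lbl))
  }

  structure(list(assessments = assessments, metrics = metrics,
                 selection = selection, breaks = breaks, ranges = ranges,
                 transitions = transitions, richness = richness,
                 failures = failures, config = config,
                 occurrence_log = occ_cells$log),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d assessment(s), %d modeled species, %d data-poor, %d failure(s)\n",
              nrow(x$assessments), nrow(x$metrics),
              length(unique(x$assessments$species)) - nrow(x$metrics),
              length(x$failures)))
  if (nrow(x$metrics))
    cat(sprintf("  mean AUC train %.3f / test %.3f\n",
                mean(x$metrics$auc_train), mean(x$metrics$auc_test)))
  decl <- summarize_declining_fraction(x)
  for (i in seq_len(nrow(decl)))
    cat(sprintf("  %s %s: %.1f%% of modeled species declining\n",
                decl$scenario[i], decl$horizon[i], 100 * decl$fraction[i]))
  invisible(x)
}

#' Fraction of modeled species losing range
#'
#' Per scenario x horizon, the fraction of model-path species with a positive
#' projected loss fraction — the headline "declining share" statistic.
#'
#' @param report A `run_report`.
#' @return Data frame: scenario, horizon, `n_declining`, `n_model`, `fraction`.
#' @export
summarize_declining_fraction <- function(report) {
  a <- report$assessments[report$assessments$path == "model_based", ]
  if (!nrow(a)) return(data.frame())
  agg <- stats::aggregate(loss_fraction ~ scenario + horizon, data = a,
                          FUN = function(L) mean(L > 0))
  n <- stats::aggregate(loss_fraction ~ scenario + horizon, data = a,
                        FUN = length)
  data.frame(scenario = agg$scenario, horizon = agg$horizon,
             n_declining = round(agg$loss_fraction * n$loss_fraction),
             n_model = n$loss_fraction, fraction = agg$loss_fraction)
}

#' Write a run report bundle
#'
#' Emits the assessment table, per-replicate metrics, the variable-selection
#' report, transition tables and richness maps under one directory with a
#' JSON manifest.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$assessments, file.path(dir, "assessments.csv"),
                   row.names = FALSE)
  if (nrow(report$metrics))
    utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                     row.names = FALSE)
  write_selection(report$selection, file.path(dir, "selection.json"),
                  file.path(dir, "correlation.csv"))
  for (lbl in names(report$transitions))
    utils::write.csv(as.data.frame(report$transitions[[lbl]]),
                     file.path(dir, sprintf("transitions_%s.csv", lbl)),
                     row.names = FALSE)
  for (lbl in names(report$richness))
    write_ascii_grid(report$richness[[lbl]]$counts,
                     report$richness[[lbl]]$grid,
                     file.path(dir, sprintf("richness_%s.asc", lbl)))
  decl <- summarize_declining_fraction(report)
  manifest <- list(
    n_species = length(unique(report$assessments$species)),
    n_modeled = nrow(report$metrics),
    failures = report$failures,
    declining = decl,
    files = list.files(dir))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.json"))
}
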