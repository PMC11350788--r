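test_that("background sampling respects the cap and the seed", {
  st <- toy_stack(10, 10)
  expect_length(sample_background(st, 1e5, 1), 100)   # cap not binding
  b <- sample_background(st, 10, 3)
  expect_length(b, 10)
  expect_false(any(duplicated(b)))
  expect_identical(b, sample_background(st, 10, 3))
  expect_false(identical(b, sample_background(st, 10, 4)))
})

test_that("a constant landscape yields the uniform model", {
  g <- nc_grid(0, 0, 60, 1, 8)
  st <- climate_stack(g, list(var1 = matrix(5, 1, 8)))
  expect_warning(
    m <- fit_maxent(c(2L, 3L), 1:8, st, fm = feature_map(st)),
    "zero variance")
  expect_true(all(m$lambda == 0))
  expect_equal(m$entropy, log(8), tolerance = 1e-12)
  p <- predict_logistic(m, st)
  # uniform q with H = log n gives p = 0.5 everywhere
  expect_equal(unique(as.vector(p$values)), 0.5, tolerance = 1e-12)
})

test_that("one binary feature reproduces the closed-form moment solution", {
  # background split 50/50 on a 0/1 feature, presence mean 0.8, no penalty:
  # the moment condition e^l / (e^l + 1) = 0.8 gives l = ln 4
  st <- strip_stack(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  fm <- feature_map(st, quadratic = FALSE)
  pres <- c(1L, 2L, 3L, 4L, 6L)       # four ones, one zero: mean 0.8
  m <- fit_maxent(pres, 1:10, st, fm = fm, beta = 0, tol = 1e-12,
                  max_iter = 200)
  expect_equal(unname(m$lambda[1]), log(4), tolerance = 1e-3)

  # a heavy L1 penalty shrinks the solution exactly to zero
  m0 <- fit_maxent(pres, 1:10, st, fm = fm, beta = 10)
  expect_equal(unname(m0$lambda[1]), 0)
})

test_that("fitted background density is normalized and matches moments", {
  st <- toy_stack(10, 10, seed = 6)
  set.seed(2)
  pres <- sample(100, 25)
  bg <- 1:100
  m <- fit_maxent(pres, bg, st, tol = 1e-9, max_iter = 300)
  fm <- m$feature_map
  zb <- features_at(fm, st, bg)
  q <- exp(drop(zb %*% m$lambda) - m$log_z)
  expect_equal(sum(q), 1, tolerance = 1e-9)
  expect_gte(m$entropy, 0)
  # KKT: fitted feature expectations match presence means within the slack
  zp <- features_at(fm, st, pres)
  gap <- abs(drop(crossprod(zb, q)) - colMeans(zp))
  expect_true(all(gap <= m$beta + 1e-6))
})

test_that("logistic output is monotone in q and reproduces training cells", {
  st <- toy_stack(10, 10, seed = 7)
  set.seed(5)
  m <- fit_maxent(sample(100, 20), 1:100, st)
  p1 <- predict_logistic(m, st)
  p2 <- predict_logistic(m, st)
  expect_identical(p1$values, p2$values)      # identity projection
  expect_true(all(p1$values >= 0 & p1$values <= 1))
  zb <- features_at(m$feature_map, st, 1:100)
  logq <- drop(zb %*% m$lambda) - m$log_z
  ord <- order(logq)
  expect_true(all(diff(as.vector(p1$values)[ord]) >= -1e-15))
})

test_that("AUC is the Mann-Whitney pair statistic", {
  expect_equal(auc(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(auc(0.5, 0.5), 0.5)
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)  # 3 of 4 pairs concordant
  expect_equal(auc(c(0.1, 0.2), c(0.8, 0.9)), 0.0)
  # ties count one half
  expect_equal(auc(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
})

test_that("the optimizer attains the brute-force optimum of its objective", {
  # <= 100-cell landscapes, <= 3 features: compare against coarse-to-fine
  # grid search over lambda on the identical penalized objective
  for (seed in 1:3) {
    st <- toy_stack(8, 8, seed = seed)
    fm <- feature_map(st, "var1")               # linear + quadratic
    set.seed(seed)
    pres <- sample(64, 12)
    bg <- 1:64
    zp <- features_at(fm, st, pres)
    zb <- features_at(fm, st, bg)
    beta <- 0.05 * apply(zb, 2, sd) / sqrt(nrow(zp))
    m <- fit_maxent(pres, bg, st, fm = fm, beta = beta, tol = 1e-10,
                    max_iter = 500)
    brute <- maxent_brute_force(zp, zb, beta)
    expect_gte(m$objective, brute - 1e-3)
    expect_lte(m$objective - brute, 0.05)       # sanity: same optimum scale
  }
})

test_that("replicate fits average logistic maps and log AUCs", {
  st <- toy_stack(12, 12, seed = 8)
  set.seed(3)
  pres <- sample(144, 30)
  fit1 <- fit_replicates(pres, st, n_replicates = 1, seed = 5,
                         background_cap = 144)
  # a single replicate equals one manual split + fit + predict
  rep_seed <- (5 + 7919L) %% .Machine$integer.max
  sp <- split_train_test(length(pres), 0.75, rep_seed)
  m <- fit_maxent(pres[sp$train], sample_background(st, 144, rep_seed), st)
  expect_equal(fit1$map$values, predict_logistic(m, st)$values,
               tolerance = 1e-12)

  fit3 <- fit_replicates(pres, st, n_replicates = 3, seed = 5,
                         background_cap = 144)
  expect_true(all(fit3$map$values >= 0 & fit3$map$values <= 1))
  expect_equal(nrow(fit3$metrics), 3)
  expect_equal(fit3$mean_auc_test, mean(fit3$metrics$auc_test))
  expect_equal(fit3$map$n_replicates, 3L)
})

test_that("projection onto a shifted stack moves suitability with climate", {
  g <- nc_grid(-180, -90, 240, 45, 90)
  st <- generate_climate(g, 2, seed = 10)
  vs <- make_virtual_species(st, c(var1 = 8, var2 = 20), diag(c(9, 900)),
                             0.05, "m")
  pres <- sample_presences(vs, 150, seed = 2)
  cells <- unique(cell_index(g, pres$lon, pres$lat))
  fit <- fit_replicates(cells, st, n_replicates = 2, seed = 4,
                        background_cap = 4000)
  warm <- apply_delta(st, scenario_delta(c(var1 = 4), "w", "x"))
  proj <- project_replicates(fit, warm)
  expect_equal(proj$scenario, "w")
  # warming shifts the suitable band; cells sitting 4 degrees below the
  # thermal optimum land exactly on it after the +4 shift and must gain
  newly_suitable <- which(abs(st$layers$var1 - 4) < 0.5)
  expect_gt(length(newly_suitable), 10)
  expect_gt(mean(proj$values[newly_suitable]),
            mean(fit$map$values[newly_suitable]))
})

test_that("jackknife gains isolate variables carrying niche signal", {
  g <- nc_grid(-180, -90, 240, 45, 90)
  st <- generate_climate(g, 3, seed = 11)
  # niche depends on var1 only; var2/var3 are decoys
  vs <- make_virtual_species(st, c(var1 = 4), matrix(9), 0.05, "jk")
  pres <- sample_presences(vs, 120, seed = 3)
  cells <- unique(cell_index(g, pres$lon, pres$lat))
  bg <- sample_background(st, 2000, 1)
  jk <- jackknife_gains(cells, bg, st)
  full <- attr(jk, "gain_full")
  drop_sig <- jk$gain_without[jk$variable == "var1"]
  drop_decoy <- jk$gain_without[jk$variable == "var3"]
  expect_lt(drop_sig, full - 0.2)              # losing the signal hurts
  expect_gt(drop_decoy, full - 0.2)            # losing a decoy does not
  expect_gt(jk$gain_only[jk$variable == "var1"],
            jk$gain_only[jk$variable == "var3"])
})
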