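small_grid <- nc_grid(-180, -90, 240, 45, 90)  # 4-degree world, fast

test_that("climate generation is a pure function of spec and seed", {
  a <- generate_climate(small_grid, 3, seed = 5)
  b <- generate_climate(small_grid, 3, seed = 5)
  expect_identical(a$layers, b$layers)
  c <- generate_climate(small_grid, 3, seed = 6)
  expect_false(identical(a$layers, c$layers))
})

test_that("injected duplicate layers exercise the correlation screen", {
  exact <- generate_climate(small_grid, 2, seed = 3, inject_duplicate = TRUE,
                            duplicate_noise_sd = 0)
  expect_equal(cor(as.vector(exact$layers$var1),
                   as.vector(exact$layers$var1_dup)), 1.0)
  noisy <- generate_climate(small_grid, 2, seed = 3, inject_duplicate = TRUE,
                            duplicate_noise_sd = 0.5)
  r <- cor(as.vector(noisy$layers$var1), as.vector(noisy$layers$var1_dup))
  expect_gt(r, 0.8)  # must trip the screening cutoff
  sel <- select_variables(noisy, r_max = 0.8, vif_max = 10, seed = 1)
  expect_length(intersect(c("var1", "var1_dup"), sel$retained), 1)
})

test_that("scenario deltas shift named layers cell-wise and are invertible", {
  st <- generate_climate(small_grid, 2, seed = 1)
  zero <- apply_delta(st, scenario_delta(c(var1 = 0), "z", "z"))
  expect_equal(zero$layers, st$layers)

  up <- apply_delta(st, scenario_delta(c(var1 = 2), "w", "2050s"))
  expect_equal(up$layers$var1, st$layers$var1 + 2)
  expect_equal(up$layers$var2, st$layers$var2)
  expect_equal(up$scenario, "w")

  back <- apply_delta(up, scenario_delta(c(var1 = -2), "b", "b"))
  expect_equal(back$layers$var1, st$layers$var1, tolerance = 1e-12)

  expect_error(apply_delta(st, scenario_delta(c(nope = 1), "x", "x")),
               "unknown variable")
})

test_that("niche suitability peaks at 1 on the niche center", {
  st <- strip_stack(c(3, 5, 7, 9, 11))
  s <- niche_suitability(st, c(var1 = 7), matrix(4))
  expect_equal(s[1, 3], 1.0)
  expect_true(all(s <= 1))
  expect_equal(s[1, 1], exp(-0.5 * 16 / 4))
})

test_that("invalid niche covariances are rejected", {
  st <- strip_stack(1:5)
  expect_error(make_virtual_species(st, c(var1 = 2), matrix(0), 0.5, "x"),
               "singular|positive definite")
  st2 <- toy_stack()
  expect_error(
    make_virtual_species(st2, c(var1 = 1, var2 = 1),
                         matrix(c(1, 2, 2, 1), 2), 0.5, "x"),
    "positive definite")
  expect_error(make_virtual_species(st, c(var1 = 2), matrix(1), 1, "x"),
               "strictly")
})

test_that("true ranges are nested superlevel sets of suitability", {
  st <- generate_climate(small_grid, 2, seed = 9)
  mu <- c(var1 = 5, var2 = 25)
  sig <- diag(c(16, 100))
  levels <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  ranges <- lapply(levels, function(s)
    make_virtual_species(st, mu, sig, s, "x")$true_range$current)
  for (i in seq_along(levels)[-1]) {
    expect_true(all(ranges[[i]] <= ranges[[i - 1]]))  # subset
    expect_lte(sum(ranges[[i]]), sum(ranges[[i - 1]]))
  }
})

test_that("presence sampling follows normalized suitability", {
  # degenerate surface: all probability mass on one cell
  st <- strip_stack(c(0, 0, 10, 0, 0))
  vs <- make_virtual_species(st, c(var1 = 10), matrix(0.01), 0.5, "pin")
  pres <- sample_presences(vs, 50, seed = 4)
  expect_equal(nrow(pres), 50)
  expect_true(all(pres$lon == cell_center(st$grid, 3L)$lon))

  pres1 <- sample_presences(vs, 1, seed = 1)
  expect_equal(nrow(pres1), 1)

  # two-level surface with suitability ratio 9:1 -> draw ratio within
  # binomial error of 9:1 at n = 500
  g <- nc_grid(0, 0, 60, 1, 2)
  suit_target <- c(0.9, 0.1)
  vals <- c(0, sqrt(-2 * log(0.1 / 0.9)))  # suitability exp(-v^2/2)
  st2 <- climate_stack(g, list(var1 = matrix(vals, 1)))
  vs2 <- make_virtual_species(st2, c(var1 = 0), matrix(1), 0.05, "two")
  set.seed(NULL)
  pres2 <- sample_presences(vs2, 500, seed = 11)
  n_high <- sum(pres2$lon == cell_center(g, 1L)$lon)
  ci <- qbinom(c(0.0005, 0.9995), 500, 0.9)
  expect_gte(n_high, ci[1])
  expect_lte(n_high, ci[2])

  # chi-square goodness of fit against normalized suitability at n = 5000
  st3 <- strip_stack(c(1, 2, 3, 4, 5))
  vs3 <- make_virtual_species(st3, c(var1 = 4), matrix(4), 0.1, "gof")
  pres3 <- sample_presences(vs3, 5000, seed = 21)
  idx <- cell_index(st3$grid, pres3$lon, pres3$lat)  # 1-row grid: index = col
  obs <- tabulate(idx, nbins = 5)
  p <- vs3$suitability[1, ] / sum(vs3$suitability[1, ])
  gof <- chisq.test(obs, p = p)
  expect_gt(gof$p.value, 0.001)

  vs0 <- make_virtual_species(strip_stack(c(100, 200)), c(var1 = 0),
                              matrix(0.0001), 0.5, "zero")
  expect_error(sample_presences(vs0, 5, seed = 1), "zero")
})

test_that("true loss fraction counts geodesic area, not cells", {
  st <- generate_climate(small_grid, 2, seed = 2)
  mu <- c(var1 = 0, var2 = 20); sig <- diag(c(25, 400))
  same <- make_virtual_species(st, mu, sig, 0.3, "a",
                               scenario_stacks = list(same = st))
  expect_equal(true_loss_fraction(same, "same"), 0.0)

  hot <- apply_delta(st, scenario_delta(c(var1 = 500), "hot", "x"))
  gone <- make_virtual_species(st, mu, sig, 0.3, "b",
                               scenario_stacks = list(hot = hot))
  expect_equal(true_loss_fraction(gone, "hot"), 1.0)

  # two-cell range, one at the equator and one at 60N; losing the northern
  # cell must lose the smaller geodesic share
  g <- nc_grid(0, -90, 60, 180, 1)
  temp <- matrix(-99, 180, 1)
  eq_row <- cell_row(g, cell_index(g, 0.5, 0.5))
  n_row <- cell_row(g, cell_index(g, 0.5, 60.5))
  temp[eq_row, 1] <- 10; temp[n_row, 1] <- 10
  cur <- climate_stack(g, list(var1 = temp))
  fut_m <- temp; fut_m[n_row, 1] <- -99
  fut <- climate_stack(g, list(var1 = fut_m), "f", "f")
  vs <- make_virtual_species(cur, c(var1 = 10), matrix(1), 0.5, "c",
                             scenario_stacks = list(f = fut))
  a_eq <- cell_area(0.5, 60); a_n <- cell_area(60.5, 60)
  expect_equal(true_loss_fraction(vs, "f"), a_n / (a_eq + a_n),
               tolerance = 1e-12)
  expect_lt(true_loss_fraction(vs, "f"), 0.5)  # area-weighted, not 1/2
})
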