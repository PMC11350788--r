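mk_range <- function(grid, cells) {
  f <- matrix(FALSE, grid$n_rows, grid$n_cols)
  f[cells] <- TRUE
  binary_range(grid, f)
}

test_that("range change handles identity, extirpation and expansion", {
  g <- nc_grid(0, 0, 60, 4, 4)
  cur <- mk_range(g, 1:4)
  expect_equal(loss_fraction(cur, cur)$loss_fraction, 0)
  expect_equal(loss_fraction(cur, mk_range(g, integer(0)))$loss_fraction, 1)
  # doubling the equal-latitude range gives L = -1 exactly
  cur_band <- mk_range(g, c(1L, 5L))      # same row -> equal cell areas
  dbl <- mk_range(g, c(1L, 5L, 9L, 13L))
  expect_equal(loss_fraction(cur_band, dbl)$loss_fraction, -1)
  expect_error(loss_fraction(mk_range(g, integer(0)), cur), "data-poor")
})

test_that("loss classification reproduces the A3(c) threshold table", {
  expect_equal(classify_loss(0.85), "CR")
  expect_equal(classify_loss(0.55), "EN")
  expect_equal(classify_loss(-0.2), "LC")
  expect_equal(
    classify_loss(c(1, 0.999, 0.8, 0.7999, 0.5, 0.4999, 0.3, 0.2999,
                    0.1, 0.0999, 0, -1)),
    c("EX", "CR", "CR", "EN", "EN", "VU", "VU", "NT",
      "NT", "LC", "LC", "LC"))
  # monotone in the threat order
  L <- seq(-0.5, 1, by = 0.01)
  ranks <- match(classify_loss(L), IUCN_LEVELS)
  expect_true(all(diff(ranks) >= 0))
  # floating-point total loss still counts as EX
  expect_equal(classify_loss(1 - 1e-14), "EX")
})

test_that("haversine distances match the spherical closed form", {
  expect_equal(distance_km(c(10, 20), c(10, 20)), 0)
  expect_equal(distance_km(c(0, 0), c(1, 0)), 6371 * pi / 180,
               tolerance = 1e-12)
  expect_equal(distance_km(c(0, 0), c(1, 0)), 111.19, tolerance = 1e-4)
  expect_equal(distance_km(c(5, 40), c(-3, 17)),
               distance_km(c(-3, 17), c(5, 40)))
  # independent oracle
  if (requireNamespace("geosphere", quietly = TRUE)) {
    p1 <- c(12.5, 41.9); p2 <- c(116.4, 39.9)
    expect_equal(distance_km(p1, p2),
                 geosphere::distHaversine(p1, p2, r = 6371000) / 1000,
                 tolerance = 1e-9)
  }
})

test_that("three-point areas follow the planar projection formula", {
  # right triangle with 1-degree legs at the equator:
  # ~ (111.19 km)^2 / 2, up to the cos(mean lat) factor on the x leg
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  km <- 6371 * pi / 180
  expect_equal(polygon_area_km2(tri),
               0.5 * km * cos(mean(tri[, 2]) * pi / 180) * km,
               tolerance = 1e-12)
  expect_equal(polygon_area_km2(tri), 6182, tolerance = 2e-3)
  # collinear -> zero; reordering invariant; duplicates warn
  expect_equal(polygon_area_km2(rbind(c(0, 0), c(1, 1), c(2, 2))), 0)
  expect_equal(polygon_area_km2(tri[c(3, 1, 2), ]), polygon_area_km2(tri))
  expect_warning(a0 <- polygon_area_km2(rbind(c(0, 0), c(0, 0), c(1, 1))),
                 "duplicate")
  expect_equal(a0, 0)
})

test_that("the data-poor cascade reproduces the printed elevation rules", {
  # three records, by enclosed area (km^2)
  expect_equal(data_poor_levels(3, 50)$levels, 3L)
  expect_equal(data_poor_levels(3, 99.9)$levels, 3L)
  expect_equal(data_poor_levels(3, 100)$levels, 2L)
  expect_equal(data_poor_levels(3, 499)$levels, 2L)
  expect_equal(data_poor_levels(3, 500)$levels, 1L)
  expect_equal(data_poor_levels(3, 9999)$levels, 1L)
  expect_equal(data_poor_levels(3, 10000)$levels, 0L)
  # two records, by distance (km)
  expect_equal(data_poor_levels(2, 9.9)$levels, 3L)
  expect_equal(data_poor_levels(2, 30)$levels, 2L)
  expect_equal(data_poor_levels(2, 499)$levels, 1L)
  expect_equal(data_poor_levels(2, 600)$levels, 0L)
  # a single record always elevates three levels
  expect_equal(data_poor_levels(1)$levels, 3L)
  # geometry is computed from points when given raw coordinates
  two <- rbind(c(0, 0), c(0.27, 0))     # ~30 km apart on the equator
  expect_equal(data_poor_levels(2, two)$levels, 2L)
  expect_error(data_poor_levels(4, 1), "model path")
})

test_that("category elevation is capped at CR and composes additively", {
  expect_equal(elevate("LC", 3), "EN")
  expect_equal(elevate("VU", 3), "CR")   # capped
  expect_equal(elevate("NT", 0), "NT")
  for (cat in c("LC", "NT", "VU", "EN", "CR")) {
    for (a in 0:3) {
      up <- elevate(cat, a)
      expect_gte(match(up, IUCN_LEVELS), match(cat, IUCN_LEVELS))
      for (b in 0:3) {
        if (a + b <= 3)
          expect_equal(elevate(up, b), elevate(cat, a + b))
      }
    }
  }
  expect_error(elevate("DD", 1))
})

test_that("species assessment routes between model and data-poor paths", {
  g <- nc_grid(0, 0, 60, 4, 4)
  cur <- mk_range(g, 1:8)
  fut <- mk_range(g, 1L)
  a <- assess_species("sp", "S", "2050s", cur, fut)
  expect_equal(a$path, "model_based")
  expect_gt(a$loss_fraction, 0.8)
  expect_equal(a$category, "CR")

  # single record, baseline LC -> EN via three-level elevation
  rec1 <- data.frame(species = "solo", lon = 5, lat = 5)
  d1 <- assess_species("solo", "S", "2050s", records = rec1)
  expect_equal(d1$path, "data_poor_single")
  expect_equal(d1$category, "EN")
  expect_equal(d1$levels_elevated, 3L)

  # zero modeled current area routes to the data-poor geometry path
  d0 <- assess_species("empty", "S", "2050s",
                       current_range = mk_range(g, integer(0)),
                       future_range = fut, records = rec1)
  expect_equal(d0$path, "data_poor_single")

  # nothing usable -> DD
  dd <- assess_species("ghost", "S", "2050s")
  expect_equal(dd$category, "DD")
})

test_that("transition tables count every species once", {
  ass <- data.frame(species = sprintf("s%d", 1:10),
                    category = c(rep("LC", 6), "NT", "NT", "VU", "CR"))
  base <- setNames(c(rep("LC", 7), "NT", "NT", "VU"), ass$species)
  tt <- transition_table(ass, base)
  expect_equal(sum(tt), 10)
  # row sums equal the baseline histogram
  expect_equal(as.vector(tt["LC", ]), as.vector(table(factor(
    ass$category[base[ass$species] == "LC"],
    levels = c("DD", IUCN_LEVELS)))))
  expect_equal(sum(tt["LC", ]), 7)
  # unchanged species sit on the diagonal
  same <- data.frame(species = names(base), category = unname(base))
  tt2 <- transition_table(same, base)
  expect_equal(sum(diag(tt2)), 10)
  # missing baseline counts from DD
  tt3 <- transition_table(ass[1, , drop = FALSE], c(other = "LC"))
  expect_equal(as.integer(tt3["DD", "LC"]), 1)
})

test_that("richness maps count overlapping ranges on the one-degree grid", {
  g <- nc_grid(0, 0, 60, 6, 6)        # native grid already at 1 degree
  r1 <- mk_range(g, cell_index(g, 2.5, 2.5))
  rm1 <- richness_map(list(a = r1))
  expect_equal(sum(rm1$counts), 1)
  expect_equal(max(rm1$counts), 1)

  r2 <- mk_range(g, c(cell_index(g, 2.5, 2.5), cell_index(g, 3.5, 2.5)))
  rm <- richness_map(list(a = r1, b = r2))
  expect_equal(max(rm$counts), 2)
  expect_equal(sum(rm$counts), 3)
  # conservation: total richness = sum over species of occupied cells
  expect_equal(sum(rm$counts), 1 + 2)

  expect_true(all(richness_change(rm, rm) == 0))

  # a 2-degree native cell overlaps a 2x2 block of one-degree cells
  g2 <- nc_grid(0, 0, 120, 3, 3)
  rc <- mk_range(g2, cell_index(g2, 3, 3))
  rmc <- richness_map(list(a = rc))
  expect_equal(sum(rmc$counts), 4)
})
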