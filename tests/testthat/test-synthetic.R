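test_that("generators are deterministic in (seed, config, grid)", {
  grid <- small_grid()
  cfg <- small_config(seed = 9)
  e1 <- generate_environment(grid, cfg)
  e2 <- generate_environment(grid, cfg)
  expect_identical(e1$elevation, e2$elevation)
  expect_identical(e1$landcover, e2$landcover)
  s1 <- generate_species_surfaces(grid, cfg, 2, e1)
  s2 <- generate_species_surfaces(grid, cfg, 2, e2)
  expect_identical(s1$current$values, s2$current$values)
  expect_identical(s1$future$values, s2$future$values)
  o1 <- generate_occupancy(s1$current, cfg)
  o2 <- generate_occupancy(s2$current, cfg)
  expect_identical(o1, o2)
  p1 <- generate_pas(grid, cfg)
  p2 <- generate_pas(grid, cfg)
  expect_identical(p1, p2)
})

test_that("environment fields honour their degenerate limits and ranges", {
  grid <- small_grid()
  flat <- small_config(seed = 1, grf_amplitude = 0, roughness = 0)
  env <- generate_environment(grid, flat)
  # pure latitudinal ramp: constant along rows, increasing northwards
  expect_equal(env$elevation[, 1], env$elevation[, ncol(env$elevation)])
  expect_true(all(diff(env$elevation[, 1]) > 0))
  expect_true(all(env$elevation >= 0))
  # one land-cover class
  one <- small_config(seed = 1, n_landcover_classes = 1)
  expect_true(all(generate_environment(grid, one)$landcover == 1L))
  # general case: classes within range, elevation non-negative
  cfg <- small_config(seed = 4)
  env2 <- generate_environment(grid, cfg)
  expect_true(all(env2$landcover %in% seq_len(cfg$n_landcover_classes)))
  expect_true(all(env2$elevation >= 0))
})

test_that("suitability lies in [0,1] and a zero shift leaves the future unchanged", {
  grid <- small_grid()
  cfg <- small_config(seed = 3)
  env <- generate_environment(grid, cfg)
  s <- generate_species_surfaces(grid, cfg, 1, env)
  expect_true(all(s$current$values >= 0 & s$current$values <= 1))
  expect_true(all(s$future$values >= 0 & s$future$values <= 1))
  frozen <- small_config(seed = 3, warming_shift = 0, elevation_shift = 0)
  s0 <- generate_species_surfaces(grid, frozen, 1,
                                  generate_environment(grid, frozen))
  expect_equal(s0$current$values, s0$future$values)
})

test_that("a positive warming shift moves suitability mass poleward", {
  grid <- small_grid()
  cfg <- small_config(seed = 6)
  env <- generate_environment(grid, cfg)
  cc <- cell_centers(grid)
  for (i in 1:3) {
    s <- generate_species_surfaces(grid, cfg, i, env)
    wmean <- function(sg) {
      v <- sg$values[cbind(cc$row, cc$col)]
      sum(v * cc$y) / sum(v)
    }
    expect_gt(wmean(s$future), wmean(s$current))
  }
})

test_that("occupancy honours its deterministic limits and favours suitable cells", {
  vals <- matrix(c(0.9, 0.7, 0.6, 0.4, 0.2, 0.1), 2, 3)
  suit <- manual_grid(vals, species_id = "sp01")
  all_cfg <- small_config(seed = 1, occupancy_rate = 1, occupancy_cut = 0)
  occ <- generate_occupancy(suit, all_cfg)
  expect_equal(nrow(occ), 6)
  # rate 1 with cut 0.5: exactly the three cells above 0.5
  cut_cfg <- small_config(seed = 1, occupancy_rate = 1, occupancy_cut = 0.5)
  occ2 <- generate_occupancy(suit, cut_cfg)
  expect_equal(nrow(occ2), 3)
  expect_true(all(vals[cbind(occ2$cell_row, occ2$cell_col)] > 0.5))
  # one seeded stochastic realisation: occupied cells are at least as suitable
  grid <- small_grid()
  cfg <- small_config(seed = 12)
  s <- generate_species_surfaces(grid, cfg, 1, generate_environment(grid, cfg))
  occ3 <- generate_occupancy(s$current, cfg)
  expect_gte(mean(s$current$values[cbind(occ3$cell_row, occ3$cell_col)]),
             mean(s$current$values))
})

test_that("protected areas stay inside the extent with the configured size law", {
  grid <- small_grid()
  ext <- grid_extent(grid)
  pas <- generate_pas(grid, small_config(seed = 2, n_pas = 100))
  expect_equal(length(unique(vapply(pas, function(p) p$id, ""))), 100)
  for (p in pas) {
    bb <- refugia:::poly_bbox(p$coords)
    expect_gte(bb["xmin"], ext["xmin"]); expect_lte(bb["xmax"], ext["xmax"])
    expect_gte(bb["ymin"], ext["ymin"]); expect_lte(bb["ymax"], ext["ymax"])
  }
  # zero log-sd: all areas equal exp(log-mean) except any clipped by the edge
  eq_cfg <- small_config(seed = 2, n_pas = 50, pa_area_log_mean = 12,
                         pa_area_log_sd = 0)
  areas <- vapply(generate_pas(grid, eq_cfg),
                  function(p) poly_area(p$coords), 0)
  expect_true(all(areas <= exp(12) * (1 + 1e-9)))
  expect_gt(mean(abs(areas / exp(12) - 1) < 1e-9), 0.9)
  # right skew: empirical median below mean for log-sd 1 over 500 PAs
  skew_cfg <- small_config(seed = 8, n_pas = 500, pa_area_log_sd = 1)
  areas2 <- vapply(generate_pas(grid, skew_cfg),
                   function(p) poly_area(p$coords), 0)
  expect_lt(median(areas2), mean(areas2))
})

test_that("habitat preferences reference classes present in the landscape", {
  grid <- small_grid()
  cfg <- small_config(seed = 5)
  env <- generate_environment(grid, cfg)
  prefs <- generate_habitat_preferences(grid, cfg, env)
  expect_true(all(prefs$class_code %in% seq_len(cfg$n_landcover_classes)))
  expect_setequal(unique(prefs$species_id), paste0("sp0", 1:3))
})
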