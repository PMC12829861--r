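test_that("habitat refinement keeps cells with any preferred fine cell and zeroes the rest", {
  vals <- matrix(0.8, 2, 2)
  suit <- manual_grid(vals, cell_size = 10, fine_factor = 2)
  lc <- matrix(1L, 4, 4)
  lc[1, 1] <- 3L  # one fine cell of class 3 inside coarse cell (1,1)
  env <- list(landcover = lc, n_landcover_classes = 3L)
  out <- refine_by_habitat(suit, env, preferred_classes = 3)
  expect_equal(out$values[1, 1], 0.8)   # retained via a single fine cell
  expect_equal(out$values[2, 2], 0)     # no preferred class present
  # preferring every class is the identity
  all_out <- refine_by_habitat(suit, env, preferred_classes = 1:3)
  expect_equal(all_out$values, vals)
})

test_that("refinement never increases scores and rejects unknown classes", {
  set.seed(7)
  grid <- small_grid()
  cfg <- small_config()
  env <- generate_environment(grid, cfg)
  suit <- generate_species_surfaces(grid, cfg, 1, env)$current
  out <- refine_by_habitat(suit, env, preferred_classes = c(1, 2))
  expect_true(all(out$values <= suit$values + 1e-15))
  expect_error(refine_by_habitat(suit, env, preferred_classes = 99),
               "unknown land-cover class code")
})

test_that("threshold is the linear-interpolation percentile of occupied scores", {
  vals <- matrix(seq(0.1, 1.0, by = 0.1), 1, 10)
  suit <- manual_grid(vals)
  occ <- data.frame(cell_col = 1:10, cell_row = 1)
  expect_equal(compute_threshold(suit, occ, 10)$tau, 0.19)
  # constant scores give the constant; a single cell gives its own score
  suit2 <- manual_grid(matrix(0.5, 1, 4))
  expect_equal(compute_threshold(suit2, data.frame(cell_col = 1:4, cell_row = 1))$tau, 0.5)
  suit3 <- manual_grid(matrix(0.7, 1, 1))
  expect_equal(compute_threshold(suit3, data.frame(cell_col = 1, cell_row = 1))$tau, 0.7)
})

test_that("threshold matches the hand-rolled percentile oracle on random score sets", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    x <- runif(n)
    p <- runif(1, 0, 100)
    suit <- manual_grid(matrix(x, 1, n))
    got <- compute_threshold(suit, data.frame(cell_col = seq_len(n), cell_row = 1), p)$tau
    expect_equal(got, percentile_oracle(x, p), tolerance = 1e-12)
  }
})

test_that("threshold errors on empty or all-missing occupancy", {
  suit <- manual_grid(matrix(c(0.2, NA), 1, 2))
  expect_error(compute_threshold(suit, data.frame(cell_col = integer(0), cell_row = integer(0))),
               "no occupied cells")
  expect_error(compute_threshold(suit, data.frame(cell_col = 2, cell_row = 1)),
               "no occupied cells")
  # missing-valued occupied cells are excluded from the order statistics
  got <- compute_threshold(suit, data.frame(cell_col = 1:2, cell_row = c(1, 1)))
  expect_equal(got$tau, 0.2)
  expect_equal(got$n_occupied_cells, 1)
})

test_that("zonal maximum picks the largest intersecting cell score", {
  vals <- matrix(c(0.2, 0.9, 0.1, 0.33), 2, 2)  # [row, col]
  suit <- manual_grid(vals, cell_size = 10)
  # spans cells (1,1) and (1,2): scores 0.2 (row1) and 0.9 (row2)
  expect_equal(pa_max_suitability(suit, pa_rect("a", 2, 2, 8, 18)), 0.9)
  # strictly inside cell (2,2): inherits 0.33
  expect_equal(pa_max_suitability(suit, pa_rect("b", 12, 13, 14, 15)), 0.33)
  # all-zero grid gives 0
  z <- manual_grid(matrix(0, 2, 2), cell_size = 10)
  expect_equal(pa_max_suitability(z, pa_rect("c", 2, 2, 8, 8)), 0)
  expect_error(pa_max_suitability(suit, pa_rect("d", 100, 100, 120, 120)),
               "outside modelled domain")
})

test_that("zonal maximum agrees with exhaustive enumeration and dominates every cell", {
  set.seed(303)
  g <- grid_spec(8, 8, cell_size = 10)
  vals <- matrix(runif(64), 8, 8)
  suit <- suitability_grid("spA", "current", g, vals)
  for (i in 1:60) {
    x0 <- runif(1, 0, 78); y0 <- runif(1, 0, 78)
    w <- runif(1, 0.5, 40); h <- runif(1, 0.5, 40)
    pa <- pa_rect("r", x0, y0, min(x0 + w, 80), min(y0 + h, 80))
    cells <- rect_cells_oracle(g, x0, y0, min(x0 + w, 80), min(y0 + h, 80))
    want <- max(vals[cbind(cells$row, cells$col)])
    got <- pa_max_suitability(suit, pa)
    expect_equal(got, want)
    expect_true(all(got >= vals[cbind(cells$row, cells$col)]))
  }
})

test_that("the batched suitability table matches individual zonal calls", {
  set.seed(11)
  grid <- small_grid()
  cfg <- small_config()
  env <- generate_environment(grid, cfg)
  species <- lapply(1:2, function(i) generate_species_surfaces(grid, cfg, i, env))
  names(species) <- vapply(species, function(s) s$current$species_id, "")
  pas <- generate_pas(grid, cfg)[1:5]
  thr <- lapply(species, function(s) {
    occ <- generate_occupancy(s$current, cfg)
    compute_threshold(s$current, occ)
  })
  tab <- build_pa_suitability_table(species, pas, thr)
  expect_equal(nrow(tab), 10)  # 2 species x 5 PAs
  expect_equal(tab, tab[order(tab$species_id, tab$pa_id), ], ignore_attr = TRUE)
  for (i in seq_len(nrow(tab))) {
    pa <- pas[[which(vapply(pas, function(p) p$id, "") == tab$pa_id[i])]]
    expect_equal(tab$max_current[i],
                 pa_max_suitability(species[[tab$species_id[i]]]$current, pa))
    expect_equal(tab$max_future[i],
                 pa_max_suitability(species[[tab$species_id[i]]]$future, pa))
  }
  # identical periods give identical maxima
  same <- lapply(species, function(s) list(current = s$current, future = s$current))
  tab2 <- build_pa_suitability_table(same, pas, thr)
  expect_equal(tab2$max_current, tab2$max_future)
})
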