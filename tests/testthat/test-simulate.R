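test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- simulation_config(n_fine_cells = 300, n_regions = 2, rng_seed = 9)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$grid$cells, s2$grid$cells)
  expect_identical(s1$pool, s2$pool)
  expect_identical(s1$occurrences, s2$occurrences)
})

test_that("landscape respects the configured altitude range and layout", {
  cfg <- simulation_config(n_fine_cells = 500, n_regions = 3,
                           altitude_range = c(115, 1602), rng_seed = 3)
  grid <- simulate_landscape(cfg)
  expect_true(all(grid$cells$altitude_m >= 115 &
                    grid$cells$altitude_m <= 1602))
  expect_equal(length(unique(grid$cells$region_id)), 3)
  # altitude-sorted slabs: region altitude ranges do not interleave
  rng <- tapply(grid$cells$altitude_m, grid$cells$region_id, range)
  expect_true(rng$R1[2] <= rng$R2[1] && rng$R2[2] <= rng$R3[1])
})

test_that("noise-free covariates are perfectly rank-correlated with altitude", {
  cfg <- simulation_config(n_fine_cells = 200, n_regions = 1,
                           n_env_vars = 1, env_altitude_loadings = 1,
                           env_noise_sd = 0, rng_seed = 4)
  grid <- simulate_landscape(cfg)
  expect_equal(cor(grid$cells$env_01, grid$cells$altitude_m,
                   method = "spearman"), 1)
})

test_that("species pool honours counts, breadth ranges and genus-group ties", {
  cfg <- simulation_config(n_species = c(rhizomatous = 5, intermediate = 5,
                                         tuberous = 5),
                           breadth_range = c(120, 120), rng_seed = 5)
  pool <- simulate_species_pool(cfg)
  expect_equal(nrow(pool), 15)
  expect_equal(unname(table(pool$group)[root_system_groups()]),
               c(5L, 5L, 5L), ignore_attr = TRUE)
  expect_true(all(pool$niche_breadth_m == 120))
  expect_equal(classify_root_system(pool$genus), pool$group)
  expect_equal(anyDuplicated(pool$taxon_id), 0)
})

test_that("degenerate configurations are rejected", {
  expect_error(simulation_config(altitude_range = c(500, 500)), "min < max")
  expect_error(simulation_config(breadth_range = c(-10, 50)), "positive")
  expect_error(simulation_config(max_occupancy_prob = 0), "0, 1")
  expect_error(simulation_config(n_env_vars = 25), "19")
})

test_that("occupancy follows the Gaussian suitability curve", {
  cfg <- simulation_config(n_fine_cells = 2000, n_regions = 1,
                           altitude_range = c(0, 1000),
                           n_species = c(rhizomatous = 1, intermediate = 0,
                                         tuberous = 0),
                           breadth_range = c(100, 100),
                           max_occupancy_prob = 1, rng_seed = 6)
  grid <- simulate_landscape(cfg)
  pool <- simulate_species_pool(cfg)
  pool$niche_center_m <- 500

  # a vanishing niche breadth confines the species to its optimum
  narrow <- pool; narrow$niche_breadth_m <- 5
  occ <- simulate_occurrences(grid, narrow, seed = 7)
  expect_true(all(abs(occ$altitude_m - 500) <= 3 * 5))

  # zero occupancy probability yields no records
  none <- pool; none$max_occupancy_prob <- 0
  expect_equal(nrow(simulate_occurrences(grid, none, seed = 7)), 0)

  # occupied-cell count sits within 4 sd of the brute-force expectation
  occ <- simulate_occurrences(grid, pool, seed = 8)
  p <- exp(-(grid$cells$altitude_m - 500)^2 / (2 * 100^2))
  expected <- sum(p)
  band <- 4 * sqrt(sum(p * (1 - p)))
  expect_lt(abs(nrow(occ) - expected), band)
})

test_that("per-band occupancy frequency converges to the suitability curve", {
  cfg <- simulation_config(n_fine_cells = 50000, n_regions = 1,
                           altitude_range = c(0, 1000),
                           n_species = c(rhizomatous = 1, intermediate = 0,
                                         tuberous = 0),
                           breadth_range = c(150, 150),
                           max_occupancy_prob = 1, rng_seed = 10)
  grid <- simulate_landscape(cfg)
  pool <- simulate_species_pool(cfg)
  pool$niche_center_m <- 500
  occ <- simulate_occurrences(grid, pool, seed = 11)

  band <- cut(grid$cells$altitude_m, seq(0, 1000, by = 50))
  occupied <- grid$cells$fine_cell_id %in% occ$fine_cell_id
  observed <- tapply(occupied, band, mean)
  expected <- tapply(gaussian_suitability(grid$cells$altitude_m, 500, 150),
                     band, mean)
  # ~2500 cells per band -> binomial sd below 0.01; allow 4 sd
  expect_lt(max(abs(observed - expected)), 0.04)
  expect_gt(cor(observed, expected), 0.999)
})
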