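test_that("weighted standardization yields weighted mean 0 and variance 1", {
  Z <- standardize_env(cbind(a = c(0, 1, 2)))
  expect_equal(unname(Z[, "a"]), c(-1, 0, 1) / sqrt(2 / 3),
               tolerance = 1e-12) # +-1.224745

  # an already standardized column is unchanged
  Z2 <- standardize_env(Z)
  expect_equal(unname(Z2[, 1]), unname(Z[, 1]), tolerance = 1e-12)

  # unequal weights
  w <- c(0.5, 0.25, 0.25)
  Zw <- standardize_env(cbind(a = c(0, 1, 2), b = c(3, -1, 4)), w)
  expect_lt(max(abs(colSums(Zw * w))), 1e-10)
  expect_lt(max(abs(colSums(Zw^2 * w) - 1)), 1e-10)

  expect_warning(Zc <- standardize_env(cbind(a = c(0, 1, 2),
                                             k = c(7, 7, 7))),
                 "constant")
  expect_equal(colnames(Zc), "a")
  expect_error(standardize_env(cbind(k = c(7, 7, 7))), "constant")
  expect_error(standardize_env(cbind(a = 1)), "2 sites")
})

test_that("the 3-site toy decomposition matches hand-computed moments", {
  Z <- standardize_env(cbind(a = c(0, 1, 2)))
  p <- niche_decompose(Z, c(0, 0.5, 0.5))
  expect_equal(p$omi, 0.375, tolerance = 1e-12)
  expect_equal(p$tol, 0.375, tolerance = 1e-12)
  expect_equal(p$inertia, 0.75, tolerance = 1e-12)
  expect_equal(p$rtol, 0, tolerance = 1e-12)
  expect_equal(tolerance_percent(p), 50)
})

test_that("a species matching the site weights sits at the origin", {
  set.seed(3)
  w_sites <- runif(20); w_sites <- w_sites / sum(w_sites)
  Z <- standardize_env(matrix(rnorm(60), 20), w_sites)
  p <- niche_decompose(Z, w_sites)
  expect_lt(p$omi, 1e-20)
  expect_true(p$degenerate)
  expect_equal(p$tol, 0)
  expect_equal(p$rtol, p$inertia)
})

test_that("inertia decomposes exactly into OMI + tolerance + residual", {
  set.seed(4)
  for (i in 1:1000) {
    n <- sample(3:12, 1); k <- sample(1:5, 1)
    Z <- matrix(rnorm(n * k), n)
    w <- rexp(n)
    p <- niche_decompose(Z, w)
    expect_lt(abs(p$inertia - (p$omi + p$tol + p$rtol)),
              1e-9 * max(p$inertia, 1))
    expect_true(p$tol >= -1e-12 && p$rtol >= -1e-9)
  }
})

test_that("zero-weight species and negative weights are rejected", {
  Z <- standardize_env(cbind(a = c(0, 1, 2)))
  expect_error(niche_decompose(Z, c(0, 0, 0)), "zero total weight")
  expect_error(niche_decompose(Z, c(-1, 1, 1)), "nonnegative")
})

test_that("SSI maps tolerance percentages onto [0, 1]", {
  expect_equal(ssi(25, 50), 0.5)
  expect_equal(ssi(0, 80), 1)
  expect_equal(ssi(80, 80), 0)
  expect_error(ssi(10, 0), "positive")
  expect_error(ssi(-2, 50), "0, t_max")
  expect_error(ssi(60, 50), "0, t_max")
  p0 <- list(tol = 0, inertia = 0)
  expect_warning(expect_equal(tolerance_percent(p0), 0), "zero inertia")
})

test_that("per-region SSI: the most tolerant species is the zero point", {
  study <- simulate_recovery_region(21, n_cells = 150)
  np <- ssi_per_region(study$occurrences, study$grid, "R1")
  expect_true(all(np$ssi >= 0 & np$ssi <= 1))
  expect_equal(np$ssi[which.max(np$tol_percent)], 0)
  expect_equal(sum(np$ssi == 0), sum(np$tol_percent == max(np$tol_percent)))
  expect_lt(max(abs(np$inertia - (np$omi + np$tol + np$rtol))), 1e-9)
})

test_that("identical occupancy gives every species SSI = 0", {
  grid <- make_test_grid(seq(105, 995, by = 10))
  rec <- make_records(rep(c("sp1", "sp2"), each = 3), "Orchis",
                      x = rep(c(3, 40, 80), 2), y = 0.5)
  rec <- assign_altitude(rec, grid)
  # with the site set wider than the shared occupancy, both species have the
  # same positive tolerance, so both sit at the generalist end: SSI = 0
  np <- ssi_per_region(rec, grid, "R1", sites = "all")
  expect_equal(np$ssi, c(0, 0))
  expect_equal(np$tol_percent[1], np$tol_percent[2])
  expect_gt(np$tol_percent[1], 0)

  # identical occupancy spanning every site is the degenerate case: zero
  # tolerance for everyone leaves Tmax = 0 and SSI undefined
  expect_error(ssi_per_region(rec, grid, "R1", sites = "occupied"),
               "t_max must be positive")
})

test_that("per-region SSI output is invariant to record order", {
  study <- simulate_recovery_region(22, n_cells = 120)
  occ <- study$occurrences
  np1 <- ssi_per_region(occ, study$grid, "R1")
  np2 <- ssi_per_region(occ[rev(seq_len(nrow(occ))), ], study$grid, "R1")
  expect_equal(np1, np2)
})

test_that("regions with fewer than two species are rejected", {
  grid <- make_test_grid(seq(105, 995, by = 10))
  rec <- assign_altitude(make_records("solo", "Orchis", x = 12, y = 0.5),
                         grid)
  expect_error(ssi_per_region(rec, grid, "R1"), "fewer than 2 species")
})

test_that("mean SSI profiles average the present group members", {
  grid <- make_test_grid(seq(105, 995, by = 10))
  iv <- build_intervals(grid, "R1")
  rec <- make_records(c("t1", "t1", "t2", "r1"),
                      c("Orchis", "Orchis", "Ophrys", "Epipactis"),
                      x = c(3.2, 40.2, 42.2, 41.2), y = 0.5)
  rec <- assign_altitude(rec, grid)
  pm <- presence_matrix(rec, iv)
  np <- data.frame(taxon_id = c("t1", "t2", "r1"),
                   ssi = c(0.2, 0.4, 0.42))
  prof <- mean_ssi_profile(np, pm, "tuberous")
  expect_equal(prof$mean_ssi[prof$index == 5], 0.3)   # (0.2 + 0.4) / 2
  expect_equal(prof$n_species[prof$index == 5], 2L)
  expect_equal(prof$mean_ssi[prof$index == 1], 0.2)   # single species
  expect_true(all(is.na(prof$mean_ssi[prof$n_species == 0])))

  prof_r <- mean_ssi_profile(np, pm, "rhizomatous")
  expect_equal(prof_r$mean_ssi[prof_r$index == 5], 0.42)

  # a present species without an SSI is a consistency error
  expect_error(mean_ssi_profile(np[-1, ], pm, "tuberous"), "lacking SSI")
})
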