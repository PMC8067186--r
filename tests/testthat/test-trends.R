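test_that("exact fits are recovered on the raw coefficient scale", {
  x <- seq(150, 1250, by = 100)
  f1 <- fit_polynomial(x, 2 * x + 1, 1)
  expect_equal(unname(f1$coefficients), c(1, 2), tolerance = 1e-8)
  expect_equal(f1$r_squared, 1)
  expect_true(f1$perfect_fit)

  f3 <- fit_polynomial(x / 100, (x / 100)^3 - 5 * (x / 100), 3)
  expect_equal(unname(f3$coefficients), c(0, -5, 0, 1), tolerance = 1e-6)
  expect_equal(f3$r_squared, 1)
})

test_that("a constant response has zero R2 and a zero top coefficient", {
  x <- seq(150, 1250, by = 100)
  for (d in 1:3) {
    f <- fit_polynomial(x, rep(2.5, length(x)), d)
    expect_equal(f$r_squared, 0)
    expect_lt(abs(f$top_coefficient), 1e-12)
  }
})

test_that("saturated or near-saturated designs are rejected", {
  expect_error(fit_polynomial(1:3, c(1, 2, 3), 2), "at least")
  expect_error(fit_polynomial(1:4, c(1, 2, 3, 4), 3), "at least")
  expect_error(fit_polynomial(c(1, 1, 2, 2, 3), rnorm(5), 3), "distinct")
  expect_error(select_trend(c(1, 2), c(1, 2)), "at least 3")
})

test_that("R2 never decreases with polynomial degree", {
  set.seed(30)
  for (i in 1:20) {
    x <- seq(150, 1450, by = 100)
    y <- rnorm(length(x))
    r2 <- sapply(1:3, function(d) fit_polynomial(x, y, d)$r_squared)
    expect_true(all(diff(r2) >= -1e-12))
  }
})

test_that("degree selection walks down cubic -> quadratic -> linear", {
  x <- seq(150, 1250, by = 100) # 12 points
  cubic <- select_trend(x, (x / 500)^3 - 5 * (x / 500))
  expect_equal(cubic$degree, 3)
  expect_equal(cubic$degree_label, "c")
  expect_equal(cubic$r_squared, 1)

  line <- select_trend(x, 3 - 0.002 * x)
  expect_equal(line$degree, 1)
  expect_equal(line$degree_label, "a")
  expect_equal(line$r_squared, 1)

  flat <- select_trend(x, rep(1, 12))
  expect_equal(flat$degree, 1)
  expect_equal(flat$significance_label, "ns")

  set.seed(31)
  noisy_quad <- select_trend(x, 1 + 0.004 * x - 2e-6 * x^2 +
                               rnorm(12, 0, 0.05))
  expect_equal(noisy_quad$degree, 2)
  expect_equal(noisy_quad$degree_label, "b")
  expect_true(noisy_quad$p_highest < 0.05)
})

test_that("the linear floor is reported even when not significant", {
  set.seed(32)
  x <- seq(150, 1450, by = 100)
  y <- rnorm(length(x)) # pure noise
  sel <- select_trend(x, y)
  expect_equal(sel$degree, 1)
  expect_true(sel$significance_label %in%
                c("ns", "p<0.05")) # noise; almost always ns
  # invariant: the selected degree is significant, or degree is 1
  expect_true(sel$degree == 1 || sel$p_highest < 0.05)
})

test_that("small samples skip the unestimable degrees", {
  x <- c(150, 250, 350, 450)
  sel <- select_trend(x, c(0, 1, 0, 1)) # 4 points: cubic skipped
  expect_true(sel$degree <= 2)
  sel3 <- select_trend(c(150, 250, 350), c(0, 1, 0)) # 3 points: linear only
  expect_equal(sel3$degree, 1)
})

test_that("fits are invariant to shuffling the (x, y) pairs", {
  set.seed(33)
  x <- seq(150, 1450, by = 100)
  y <- 1 + 0.004 * x - 2e-6 * x^2 + rnorm(length(x), 0, 0.05)
  a <- select_trend(x, y)
  perm <- sample(length(x))
  b <- select_trend(x[perm], y[perm])
  expect_equal(a$degree, b$degree)
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-9)
  expect_equal(a$r_squared, b$r_squared, tolerance = 1e-12)
})

test_that("missing responses are dropped pairwise before fitting", {
  x <- seq(150, 1450, by = 100)
  y <- 2 + 0.001 * x
  y[c(3, 7)] <- NA
  sel <- select_trend(x, y)
  expect_equal(sel$n_points, 12)
  expect_equal(sel$r_squared, 1)
})

test_that("trend tables cover every region-group combination with data", {
  study <- simulate_study(simulation_config(n_fine_cells = 1200,
                                            n_regions = 2, rng_seed = 17))
  fit <- alti_gradient(study$occurrences, study$grid)
  tr <- fit$trends
  expect_setequal(unique(tr$response), c("density", "mean_ssi"))
  dens <- tr[tr$response == "density", ]
  expect_equal(nrow(dens), 2 * 4) # 2 regions x (all + 3 groups)
  expect_true(all(tr$degree %in% 1:3))
  expect_equal(tr$degree_label,
               c("a", "b", "c")[tr$degree])
  fits <- attr(tr, "fits")
  expect_equal(length(fits), nrow(tr))
  # predict on the fitted object reproduces the stored R2
  f <- fits[[1]]
  key <- strsplit(names(fits)[1], "|", fixed = TRUE)[[1]]
  sub <- fit$density[fit$density$region_id == key[1] &
                       fit$density$group == key[2], ]
  r2 <- 1 - sum((sub$density - predict(f, sub$midpoint_m))^2) /
    sum((sub$density - mean(sub$density))^2)
  expect_equal(r2, f$r_squared, tolerance = 1e-6)
})
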