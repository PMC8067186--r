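# Fixtures built in code and the independent brute-force niche oracle.

# A small rectangular landscape: cells on a unit lattice with explicit
# altitudes (recycled), one env covariate proportional to altitude.
make_test_grid <- function(altitudes, region_id = "R1", cell_area = 1,
                           env = TRUE, ids = NULL) {
  n <- length(altitudes)
  cells <- data.frame(
    fine_cell_id = if (is.null(ids)) sprintf("C%03d", seq_len(n)) else ids,
    x = seq_len(n) - 0.5,
    y = 0.5,
    altitude_m = altitudes,
    region_id = rep_len(region_id, n),
    stringsAsFactors = FALSE
  )
  if (env) cells$env_01 <- altitudes / 100
  landscape_grid(cells, fine_cell_area_km2 = cell_area)
}

make_records <- function(taxon_id, genus, x, y, ...) {
  data.frame(taxon_id = taxon_id, genus = genus,
             group = classify_root_system(genus),
             x = x, y = y, ..., stringsAsFactors = FALSE)
}

# Brute-force Outlying Mean Index decomposition: explicit loops over sites
# and variables, no matrix algebra. Kept deliberately independent of
# niche_decompose() so it can serve as its oracle.
omi_oracle <- function(Z, weights) {
  n <- nrow(Z); p <- ncol(Z)
  w <- weights / sum(weights)
  u <- numeric(p)
  for (k in seq_len(p)) {
    for (j in seq_len(n)) u[k] <- u[k] + w[j] * Z[j, k]
  }
  omi <- 0
  for (k in seq_len(p)) omi <- omi + u[k] * u[k]
  inertia <- 0
  for (j in seq_len(n)) {
    ssq <- 0
    for (k in seq_len(p)) ssq <- ssq + Z[j, k]^2
    inertia <- inertia + w[j] * ssq
  }
  tol <- 0
  if (omi >= 1e-12) {
    nu <- sqrt(omi)
    for (j in seq_len(n)) {
      proj <- 0
      for (k in seq_len(p)) proj <- proj + Z[j, k] * u[k]
      proj <- proj / nu
      tol <- tol + w[j] * (proj - nu)^2
    }
  }
  list(inertia = inertia, omi = omi, tol = tol,
       rtol = inertia - omi - tol)
}

# Recovery experiment: one region, niche breadths spanning [30, 300] m and
# centers confined to the central band of the gradient so that Gaussian
# niches are not truncated at the gradient edges.
simulate_recovery_region <- function(seed, n_cells = 500,
                                     center_band = c(500, 1200),
                                     breadth_range = c(30, 300)) {
  sim <- simulation_config(
    n_fine_cells = n_cells, n_regions = 1,
    n_species = c(rhizomatous = 10, intermediate = 10, tuberous = 10),
    breadth_range = breadth_range, max_occupancy_prob = 1, rng_seed = seed)
  grid <- simulate_landscape(sim)
  pool <- simulate_species_pool(sim)
  set.seed(seed + 10)
  pool$niche_center_m <- runif(nrow(pool), center_band[1], center_band[2])
  occ <- simulate_occurrences(grid, pool, seed = seed + 2)
  list(grid = grid, pool = pool, occurrences = occ)
}
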