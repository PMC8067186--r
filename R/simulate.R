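## Virtual landscapes and virtual species with Gaussian altitudinal niches.
## The simulator supplies ground-truth niche breadths so that the whole
## binning -> density -> niche -> trend chain can be validated against known
## parameters, in place of access-restricted national occurrence databases.

#' Configuration for the landscape and species simulator
#'
#' Defaults emulate a temperate central-European study area: altitudes
#' spanning 115-1602 m a.s.l., six biogeographic regions arranged as
#' altitudinal slabs (thermo-, meso- and oreophyticum zonation), 19
#' altitude-correlated bioclimate-like covariates, and a 69-taxon orchid
#' flora split into rhizomatous, intermediate and tuberous rooting-system
#' groups.
#'
#' @param n_fine_cells Number of fine grid cells.
#' @param n_regions Number of regions (altitude-contiguous by default).
#' @param altitude_range Numeric length-2, min and max altitude in meters.
#' @param n_env_vars Number of environmental covariates (<= 19).
#' @param env_altitude_loadings Signed slopes of each covariate on
#'   standardized altitude; recycled/truncated to \code{n_env_vars}.
#' @param env_noise_sd Standard deviation of the Gaussian noise added to
#'   each covariate (on the standardized-altitude scale).
#' @param n_species Named integer vector: species counts per rooting-system
#'   group.
#' @param breadth_range Either a length-2 numeric range of niche breadths
#'   (sigma of the Gaussian suitability curve, meters) applied to every
#'   group, or a named list of per-group ranges.
#' @param max_occupancy_prob Occupancy probability at the niche optimum,
#'   in (0, 1].
#' @param region_layout \code{"altitude"} for contiguous altitude-sorted
#'   slabs, \code{"random"} for a random partition of cells into regions.
#' @param mapping_cell_size Side length of the coarse mapping-grid cells in
#'   lattice units (fine cells sit on a unit lattice).
#' @param fine_cell_area_km2 Area of one fine cell, km2.
#' @param rng_seed Integer seed; every simulation is deterministic given it.
#' @return A validated list of class \code{sim_config}.
#' @export
simulation_config <- function(n_fine_cells = 6000,
                              n_regions = 6,
                              altitude_range = c(115, 1602),
                              n_env_vars = 19,
                              env_altitude_loadings = NULL,
                              env_noise_sd = 0.3,
                              n_species = c(rhizomatous = 30,
                                            intermediate = 21,
                                            tuberous = 18),
                              breadth_range = c(50, 300),
                              max_occupancy_prob = 0.8,
                              region_layout = c("altitude", "random"),
                              mapping_cell_size = 2.5,
                              fine_cell_area_km2 = 1,
                              rng_seed = 1L) {
  region_layout <- match.arg(region_layout)
  if (length(altitude_range) != 2 ||
      !all(is.finite(altitude_range)) ||
      altitude_range[1] >= altitude_range[2]) {
    stop("altitude_range must be (min, max) with min < max", call. = FALSE)
  }
  if (n_env_vars < 0 || n_env_vars > 19) {
    stop("n_env_vars must be between 0 and 19", call. = FALSE)
  }
  if (n_fine_cells < 1 || n_regions < 1) {
    stop("n_fine_cells and n_regions must be positive", call. = FALSE)
  }
  groups <- root_system_groups()
  if (is.null(names(n_species))) names(n_species) <- groups[seq_along(n_species)]
  if (!all(names(n_species) %in% groups) || any(n_species < 0)) {
    stop("n_species must be a named, nonnegative vector over the ",
         "rooting-system groups", call. = FALSE)
  }
  if (!is.list(breadth_range)) {
    breadth_range <- stats::setNames(
      rep(list(breadth_range), length(n_species)), names(n_species))
  }
  for (g in names(n_species)) {
    br <- breadth_range[[g]]
    if (is.null(br) || length(br) != 2 || any(br <= 0) || br[1] > br[2]) {
      stop("breadth_range for group '", g,
           "' must be a positive (lo, hi) pair", call. = FALSE)
    }
  }
  if (max_occupancy_prob <= 0 || max_occupancy_prob > 1) {
    stop("max_occupancy_prob must be in (0, 1]", call. = FALSE)
  }
  if (is.null(env_altitude_loadings)) {
    # alternating-sign slopes: lapse-rate-like negatives interleaved with
    # precipitation-like positives, tapering in strength
    env_altitude_loadings <- rep(c(-1, 1), length.out = 19) *
      seq(0.95, 0.35, length.out = 19)
  }
  env_altitude_loadings <- rep(env_altitude_loadings,
                               length.out = n_env_vars)
  structure(
    list(n_fine_cells = as.integer(n_fine_cells),
         n_regions = as.integer(n_regions),
         altitude_range = as.numeric(altitude_range),
         n_env_vars = as.integer(n_env_vars),
         env_altitude_loadings = as.numeric(env_altitude_loadings),
         env_noise_sd = as.numeric(env_noise_sd),
         n_species = n_species,
         breadth_range = breadth_range,
         max_occupancy_prob = as.numeric(max_occupancy_prob),
         region_layout = region_layout,
         mapping_cell_size = as.numeric(mapping_cell_size),
         fine_cell_area_km2 = as.numeric(fine_cell_area_km2),
         rng_seed = as.integer(rng_seed)),
    class = "sim_config"
  )
}

#' Simulate a landscape grid
#'
#' Cells sit on a unit lattice; altitude increases (stochastically) along
#' the x axis so that the default altitude-sorted regions are also spatially
#' contiguous strips. Each environmental covariate is
#' \code{loading * standardized(altitude) + N(0, env_noise_sd)}.
#'
#' @param config A [simulation_config()].
#' @return A \code{landscape_grid}.
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  n <- config$n_fine_cells
  nx <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  x <- (idx %/% nx) + 0.5  # column-major: x advances slowest
  y <- (idx %% nx) + 0.5

  alt <- sort(stats::runif(n, config$altitude_range[1],
                           config$altitude_range[2]))
  # cells are already ordered by (x, y); sorted altitudes make altitude
  # increase along x
  region_of <- ceiling(seq_len(n) / (n / config$n_regions))
  if (config$region_layout == "random") {
    region_of <- region_of[sample.int(n)]
  }
  cells <- data.frame(
    fine_cell_id = sprintf("C%06d", seq_len(n)),
    x = x, y = y,
    altitude_m = alt,
    region_id = sprintf("R%d", region_of),
    stringsAsFactors = FALSE
  )
  if (config$n_env_vars > 0) {
    z <- as.numeric(scale(alt))
    for (k in seq_len(config$n_env_vars)) {
      cells[[sprintf("env_%02d", k)]] <-
        config$env_altitude_loadings[k] * z +
        stats::rnorm(n, 0, config$env_noise_sd)
    }
  }
  grid <- landscape_grid(cells,
                         fine_cell_area_km2 = config$fine_cell_area_km2)
  assign_mapping_cells(grid, config$mapping_cell_size)
}

#' Simulate a virtual species pool
#'
#' Each species gets a genus drawn from its group's genus list (so that
#' rooting-system classification works downstream), a niche center uniform
#' over the altitude range and a niche breadth uniform over the group's
#' breadth range.
#'
#' @param config A [simulation_config()].
#' @return Data frame with columns \code{taxon_id, genus, group,
#'   niche_center_m, niche_breadth_m, max_occupancy_prob}.
#' @export
simulate_species_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 1L)
  lookup <- root_system_lookup()
  pool <- lapply(names(config$n_species), function(g) {
    ng <- config$n_species[[g]]
    if (ng == 0) return(NULL)
    genera <- lookup$genus[lookup$group == g]
    genus <- genera[(seq_len(ng) - 1L) %% length(genera) + 1L]
    br <- config$breadth_range[[g]]
    data.frame(
      taxon_id = sprintf("%s_vsp%02d", genus, seq_len(ng)),
      genus = genus,
      group = g,
      niche_center_m = stats::runif(ng, config$altitude_range[1],
                                    config$altitude_range[2]),
      niche_breadth_m = stats::runif(ng, br[1], br[2]),
      max_occupancy_prob = config$max_occupancy_prob,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pool)
  rownames(out) <- NULL
  out
}

#' Simulate presence-only occurrence records
#'
#' A species occupies fine cell j with probability
#' \code{max_occupancy_prob * exp(-(alt_j - center)^2 / (2 * breadth^2))},
#' independently across cells; one record is emitted per occupied cell
#' (presence, not abundance).
#'
#' @param grid A \code{landscape_grid}.
#' @param pool Species pool from [simulate_species_pool()].
#' @param seed Integer seed for the occupancy draws.
#' @return Occurrence data frame in the layout of [read_occurrences()].
#' @export
simulate_occurrences <- function(grid, pool, seed = 1L) {
  stopifnot(inherits(grid, "landscape_grid"), is.data.frame(pool))
  set.seed(seed)
  cells <- grid$cells
  recs <- vector("list", nrow(pool))
  for (i in seq_len(nrow(pool))) {
    p <- gaussian_suitability(cells$altitude_m,
                              pool$niche_center_m[i],
                              pool$niche_breadth_m[i],
                              pool$max_occupancy_prob[i])
    occ <- stats::runif(nrow(cells)) < p
    if (!any(occ)) next
    recs[[i]] <- data.frame(
      taxon_id = pool$taxon_id[i],
      genus = pool$genus[i],
      group = pool$group[i],
      x = cells$x[occ],
      y = cells$y[occ],
      region_id = cells$region_id[occ],
      altitude_m = cells$altitude_m[occ],
      fine_cell_id = cells$fine_cell_id[occ],
      mapping_cell_id = cells$mapping_cell_id[occ],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- utils::read.csv(text = paste(occurrence_columns, collapse = ","))
  }
  rownames(out) <- NULL
  out[occurrence_columns]
}

#' Gaussian suitability curve
#'
#' @param altitude_m Altitudes at which to evaluate the curve.
#' @param center_m Niche optimum in meters.
#' @param breadth_m Niche breadth (sigma) in meters, > 0.
#' @param max_prob Occupancy probability at the optimum.
#' @return Occupancy probabilities.
#' @export
gaussian_suitability <- function(altitude_m, center_m, breadth_m,
                                 max_prob = 1) {
  stopifnot(breadth_m > 0, max_prob >= 0, max_prob <= 1)
  max_prob * exp(-(altitude_m - center_m)^2 / (2 * breadth_m^2))
}

#' Simulate a full synthetic study system
#'
#' Convenience wrapper: landscape, species pool and occurrences from one
#' config, plus the ground-truth table used by parameter-recovery tests.
#'
#' @param config A [simulation_config()].
#' @return List with \code{grid}, \code{pool} (the ground truth) and
#'   \code{occurrences}.
#' @export
simulate_study <- function(config = simulation_config()) {
  grid <- simulate_landscape(config)
  pool <- simulate_species_pool(config)
  occ <- simulate_occurrences(grid, pool, seed = config$rng_seed + 2L)
  list(grid = grid, pool = pool, occurrences = occ)
}
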