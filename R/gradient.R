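## The top-level analysis: one call takes occurrence records plus a
## landscape grid and returns binning, density, niche/SSI and trend results
## for every region, as a classed object with the usual model-object verbs.

#' Altitudinal gradient analysis of richness and specialization
#'
#' Runs the full analysis chain for each region of the grid: records are
#' snapped to grid cells (unless already annotated), altitudes are binned
#' into vertical intervals with cell-count areas, area-adjusted densities
#' and per-species SSI values are computed, group-wise mean-SSI profiles are
#' formed, and altitude trends are fitted to both responses by
#' significance-driven polynomial degree selection.
#'
#' @param occurrences Occurrence records (see [read_occurrences()] or
#'   [simulate_occurrences()]).
#' @param grid A \code{landscape_grid}.
#' @param regions Regions to analyse; default all regions of the grid that
#'   hold at least 2 species on at least 2 sites.
#' @param groups Rooting-system groups to profile.
#' @param alpha Significance level of the polynomial degree selection.
#' @param log_base Base of the area logarithm in the density formula.
#' @param interval_width Vertical interval width in meters.
#' @param sites Site set for the niche decomposition, \code{"occupied"} or
#'   \code{"all"} (see [ssi_per_region()]).
#' @param tmax_scope \code{"region"} (default) takes Tmax within each
#'   region; \code{"global"} uses one Tmax across all analysed regions.
#' @return Object of class \code{alti_gradient} with elements
#'   \code{intervals}, \code{presence}, \code{density}, \code{niche},
#'   \code{ssi_profiles}, \code{occupancy}, \code{trends} (with fitted
#'   \code{alti_trend} objects in its \code{"fits"} attribute) and
#'   \code{config}.
#' @export
#' @examples
#' study <- simulate_study(simulation_config(n_fine_cells = 800,
#'                                           n_regions = 2, rng_seed = 7))
#' fit <- alti_gradient(study$occurrences, study$grid)
#' fit
alti_gradient <- function(occurrences, grid,
                          regions = NULL,
                          groups = root_system_groups(),
                          alpha = 0.05,
                          log_base = 10,
                          interval_width = 100,
                          sites = c("occupied", "all"),
                          tmax_scope = c("region", "global")) {
  stopifnot(inherits(grid, "landscape_grid"))
  sites <- match.arg(sites)
  tmax_scope <- match.arg(tmax_scope)
  if (interval_width <= 0) stop("interval_width must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)

  needs_assign <- !all(c("altitude_m", "fine_cell_id", "region_id") %in%
                         names(occurrences)) ||
    anyNA(occurrences$altitude_m) || anyNA(occurrences$fine_cell_id) ||
    anyNA(occurrences$region_id)
  if (needs_assign) occurrences <- assign_altitude(occurrences, grid)

  if (is.null(regions)) {
    regions <- sort(unique(occurrences$region_id))
    usable <- vapply(regions, function(r) {
      rr <- occurrences[occurrences$region_id == r, , drop = FALSE]
      length(unique(rr$taxon_id)) >= 2 &&
        length(unique(rr$fine_cell_id)) >= 2
    }, logical(1))
    regions <- regions[usable]
  }
  if (!length(regions)) stop("no analysable regions", call. = FALSE)

  intervals <- list(); presence <- list(); density <- list()
  niche <- list(); pms <- list()
  for (r in regions) {
    iv <- build_intervals(grid, r, width = interval_width)
    pm <- presence_matrix(occurrences, iv, width = interval_width)
    intervals[[r]] <- iv
    pms[[r]] <- pm
    presence[[r]] <- presence_long(pm)
    density[[r]] <- density_profiles(pm, groups = c("all", groups),
                                     log_base = log_base)
    niche[[r]] <- ssi_per_region(occurrences, grid, r, sites = sites)
  }
  niche_df <- do.call(rbind, niche)
  if (tmax_scope == "global") {
    t_max <- max(niche_df$tol_percent)
    niche_df$ssi <- ssi(niche_df$tol_percent, t_max)
  }

  ssi_profiles <- list()
  for (r in regions) {
    np <- niche_df[niche_df$region_id == r, , drop = FALSE]
    for (g in groups) {
      ssi_profiles[[paste(r, g)]] <- mean_ssi_profile(np, pms[[r]], g)
    }
  }
  ssi_df <- do.call(rbind, ssi_profiles)
  density_df <- do.call(rbind, density)
  rownames(niche_df) <- rownames(ssi_df) <- rownames(density_df) <- NULL

  trends_density <- fit_trend_table(density_df, "density", alpha = alpha)
  trends_ssi <- fit_trend_table(ssi_df, "mean_ssi", alpha = alpha)
  trends <- rbind(trends_density, trends_ssi)
  rownames(trends) <- NULL
  attr(trends, "fits") <- c(attr(trends_density, "fits"),
                            attr(trends_ssi, "fits"))

  occupancy <- NULL
  if (!is.na(n_mapping_cells(grid))) {
    occupancy <- occupancy_summary(occurrences, grid)
  }

  structure(
    list(intervals = do.call(rbind, c(intervals, make.row.names = FALSE)),
         presence = do.call(rbind, c(presence, make.row.names = FALSE)),
         density = density_df,
         niche = niche_df,
         ssi_profiles = ssi_df,
         occupancy = occupancy,
         trends = trends,
         occurrences = occurrences,
         config = list(regions = regions, groups = groups, alpha = alpha,
                       log_base = log_base,
                       interval_width = interval_width, sites = sites,
                       tmax_scope = tmax_scope)),
    class = "alti_gradient"
  )
}

#' @export
print.alti_gradient <- function(x, ...) {
  cat("Altitudinal gradient analysis\n")
  cat("  regions:", paste(x$config$regions, collapse = ", "), "\n")
  cat("  taxa:", length(unique(x$niche$taxon_id)),
      " records:", nrow(x$occurrences), "\n")
  cat("  vertical intervals:", nrow(x$intervals), "of",
      x$config$interval_width, "m\n")
  cat("  trends fitted:", nrow(x$trends),
      sprintf("(alpha = %g)\n", x$config$alpha))
  if (!is.null(x$occupancy)) {
    all_row <- x$occupancy[x$occupancy$group == "all", ]
    cat(sprintf("  occupancy: %d of %d mapping cells (%.1f%%)\n",
                all_row$occupied, all_row$total, all_row$percent))
  }
  invisible(x)
}

#' @export
summary.alti_gradient <- function(object, ...) {
  structure(list(trends = object$trends, occupancy = object$occupancy,
                 niche = object$niche, config = object$config),
            class = "summary.alti_gradient")
}

#' @export
print.summary.alti_gradient <- function(x, ...) {
  if (!is.null(x$occupancy)) {
    cat("Mapping-grid occupancy:\n")
    print(x$occupancy, row.names = FALSE)
    cat("\n")
  }
  cat("Selected altitude trends (R2, degree a/b/c, significance):\n")
  tr <- x$trends
  tr$r_squared <- round(tr$r_squared, 2)
  tr$p_highest <- signif(tr$p_highest, 2)
  print(tr, row.names = FALSE)
  cat("\nSSI by group (regional means):\n")
  print(round(tapply(x$niche$ssi, list(x$niche$region_id, x$niche$group),
                     mean), 3))
  invisible(x)
}

#' @export
coef.alti_gradient <- function(object, ...) {
  lapply(attr(object$trends, "fits"), stats::coef)
}

#' Plot altitudinal profiles with fitted trends
#'
#' Draws the per-group response profile of each region against the interval
#' midpoint, overlaying the selected polynomial trend.
#'
#' @param x An \code{alti_gradient} object.
#' @param response \code{"density"} or \code{"mean_ssi"}.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.alti_gradient <- function(x, response = c("density", "mean_ssi"),
                               ...) {
  response <- match.arg(response)
  prof <- if (response == "density") x$density else x$ssi_profiles
  regions <- x$config$regions
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(regions)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  groups <- unique(prof$group)
  cols <- stats::setNames(grDevices::hcl.colors(length(groups), "Dark 3"),
                          groups)
  fits <- attr(x$trends, "fits")
  for (r in regions) {
    pr <- prof[prof$region_id == r, ]
    graphics::plot(pr$midpoint_m, pr[[response]], col = cols[pr$group],
                   pch = 16, xlab = "altitude (m)", ylab = response,
                   main = r, ...)
    for (g in groups) {
      key <- paste(r, g, response, sep = "|")
      if (is.null(fits[[key]])) next
      xx <- seq(min(pr$midpoint_m), max(pr$midpoint_m), length.out = 100)
      graphics::lines(xx, predict(fits[[key]], xx), col = cols[g])
    }
  }
  invisible(x)
}
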