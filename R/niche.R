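## Outlying Mean Index niche decomposition and the species specialization
## index (SSI).
##
## For a species with site weights w_j over standardized environmental site
## scores z_j (weighted mean 0, weighted variance 1 per column):
##   centroid      u    = sum_j w_j z_j
##   marginality   OMI  = ||u||^2            (distance from average habitat)
##   inertia       I    = sum_j w_j ||z_j||^2
##   tolerance     Tol  = sum_j w_j (s_j - ||u||)^2, s_j = z_j . u / ||u||
##   residual tol  Rtol = I - OMI - Tol      (variance off the marginality axis)
## Tolerance as a percentage of inertia feeds SSI = 1 - T/Tmax.

#' Weighted standardization of an environmental matrix
#'
#' Centers and scales each column to weighted mean 0 and weighted variance 1
#' under the given site weights. Constant columns carry no niche information
#' and are dropped with a warning.
#'
#' @param env Numeric matrix or data frame, sites in rows, environmental
#'   variables (altitude plus bioclimate-like covariates) in columns.
#' @param site_weights Nonnegative site weights; normalized to sum 1.
#' @return Numeric matrix of weighted z-scores with a
#'   \code{"site_weights"} attribute.
#' @export
standardize_env <- function(env, site_weights = NULL) {
  Z <- as.matrix(env)
  storage.mode(Z) <- "double"
  if (nrow(Z) < 2) stop("need at least 2 sites", call. = FALSE)
  if (is.null(site_weights)) site_weights <- rep(1, nrow(Z))
  stopifnot(length(site_weights) == nrow(Z), all(site_weights >= 0),
            sum(site_weights) > 0)
  w <- site_weights / sum(site_weights)
  m <- colSums(Z * w)
  Zc <- sweep(Z, 2, m)
  v <- colSums(Zc^2 * w)
  constant <- v <= 1e-12 * pmax(m^2, 1)
  if (all(constant)) {
    stop("all environmental columns are constant", call. = FALSE)
  }
  if (any(constant)) {
    warning("dropping constant environmental column(s): ",
            paste(colnames(Z)[constant], collapse = ", "), call. = FALSE)
    Zc <- Zc[, !constant, drop = FALSE]
    v <- v[!constant]
  }
  Zs <- sweep(Zc, 2, sqrt(v), "/")
  attr(Zs, "site_weights") <- w
  Zs
}

#' Niche decomposition of one species
#'
#' Decomposes a species' environmental inertia into marginality (OMI),
#' tolerance along the marginality axis, and residual tolerance, given
#' standardized site scores and the species' site weights. When marginality
#' is numerically zero the marginality axis is undefined; tolerance is then
#' set to 0, all non-marginal inertia goes to residual tolerance, and the
#' species is flagged \code{degenerate}.
#'
#' @param Z Standardized site-by-variable matrix (see [standardize_env()]).
#' @param species_weights Nonnegative weights over the rows of \code{Z}
#'   (typically 1 for occupied sites, 0 elsewhere); normalized to sum 1.
#' @return List with \code{inertia}, \code{omi}, \code{tol}, \code{rtol}
#'   and logical \code{degenerate}.
#' @export
niche_decompose <- function(Z, species_weights) {
  Z <- as.matrix(Z)
  stopifnot(length(species_weights) == nrow(Z))
  if (any(species_weights < 0)) {
    stop("species weights must be nonnegative", call. = FALSE)
  }
  total <- sum(species_weights)
  if (total <= 0) stop("species has zero total weight", call. = FALSE)
  w <- species_weights / total

  u <- colSums(Z * w)
  omi <- sum(u^2)
  inertia <- sum(rowSums(Z^2) * w)
  if (omi < 1e-12) {
    return(list(inertia = inertia, omi = omi, tol = 0,
                rtol = inertia - omi, degenerate = TRUE))
  }
  s <- drop(Z %*% u) / sqrt(omi)  # projection onto the marginality axis
  tol <- sum(w * (s - sqrt(omi))^2)
  list(inertia = inertia, omi = omi, tol = tol,
       rtol = inertia - omi - tol, degenerate = FALSE)
}

#' Tolerance as a percentage of inertia
#'
#' @param params Output of [niche_decompose()] (or any list with
#'   \code{tol} and \code{inertia}).
#' @return \code{100 * tol / inertia}; a species with zero inertia (all its
#'   sites at the environmental origin) gets 0 with a warning.
#' @export
tolerance_percent <- function(params) {
  if (params$inertia <= 0) {
    warning("species with zero inertia; tolerance percentage set to 0",
            call. = FALSE)
    return(0)
  }
  100 * params$tol / params$inertia
}

#' Species specialization index
#'
#' \deqn{SSI = 1 - T_i / T_{max}}
#' where \eqn{T_i} is species i's tolerance percentage and \eqn{T_{max}}
#' the maximum tolerance percentage among the species of the region. SSI is
#' 1 for the extreme specialist (zero tolerance) and 0 for the extreme
#' generalist (the species attaining \eqn{T_{max}}).
#'
#' @param t_i Tolerance percentage(s) of the focal species.
#' @param t_max Maximum tolerance percentage in the species set, > 0.
#' @return SSI value(s) in [0, 1].
#' @export
#' @examples
#' ssi(25, 50) # 0.5
ssi <- function(t_i, t_max) {
  if (t_max <= 0) {
    stop("t_max must be positive (no tolerance variation among species)",
         call. = FALSE)
  }
  if (any(t_i < 0) || any(t_i > t_max + 1e-9)) {
    stop("t_i must lie in [0, t_max]", call. = FALSE)
  }
  1 - pmin(t_i, t_max) / t_max
}

#' Per-region niche parameters and SSI for every species
#'
#' Runs the niche decomposition for each species of one region. Sites are
#' the region's fine cells — by default only those occupied by at least one
#' record (presence-only data carry no information about unvisited cells) —
#' with uniform site weights; each species is weighted uniformly over its
#' own occupied sites. Tmax is taken across all species of the region,
#' rooting-system groups pooled.
#'
#' @param records Occurrence records annotated with \code{fine_cell_id} and
#'   \code{region_id}.
#' @param grid A \code{landscape_grid} providing altitude and the
#'   environmental covariates.
#' @param region_id Region to analyse.
#' @param sites \code{"occupied"} (default) restricts the site set to cells
#'   holding at least one record; \code{"all"} uses every cell of the
#'   region.
#' @param t_max Optional externally supplied Tmax (e.g. a global maximum
#'   across regions); default is the regional maximum.
#' @return Data frame with one row per species: \code{region_id, taxon_id,
#'   group, n_sites, inertia, omi, tol, rtol, tol_percent, ssi,
#'   degenerate}.
#' @export
ssi_per_region <- function(records, grid, region_id,
                           sites = c("occupied", "all"), t_max = NULL) {
  sites <- match.arg(sites)
  stopifnot(inherits(grid, "landscape_grid"))
  recs <- records[!is.na(records$region_id) &
                    records$region_id == region_id, , drop = FALSE]
  taxa <- sort(unique(recs$taxon_id))
  if (length(taxa) < 2) {
    stop("region ", region_id, " has fewer than 2 species with records",
         call. = FALSE)
  }
  cells <- grid$cells[grid$cells$region_id == region_id, , drop = FALSE]
  if (sites == "occupied") {
    cells <- cells[cells$fine_cell_id %in% recs$fine_cell_id, ,
                   drop = FALSE]
  }
  if (nrow(cells) < 2) {
    stop("region ", region_id, " has fewer than 2 ", sites, " sites",
         call. = FALSE)
  }
  env <- as.matrix(cells[, c("altitude_m", grid$env_vars), drop = FALSE])
  Z <- standardize_env(env)

  params <- lapply(taxa, function(tx) {
    occ_cells <- unique(recs$fine_cell_id[recs$taxon_id == tx])
    wts <- as.numeric(cells$fine_cell_id %in% occ_cells)
    if (sum(wts) == 0) {
      stop("species ", tx, " has no records on the site set", call. = FALSE)
    }
    p <- niche_decompose(Z, wts)
    data.frame(
      region_id = region_id,
      taxon_id = tx,
      group = recs$group[match(tx, recs$taxon_id)],
      n_sites = as.integer(sum(wts > 0)),
      inertia = p$inertia, omi = p$omi, tol = p$tol, rtol = p$rtol,
      tol_percent = tolerance_percent(p),
      degenerate = p$degenerate,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, params)
  if (is.null(t_max)) t_max <- max(out$tol_percent)
  out$ssi <- ssi(out$tol_percent, t_max)
  rownames(out) <- NULL
  out[c("region_id", "taxon_id", "group", "n_sites", "inertia", "omi",
        "tol", "rtol", "tol_percent", "ssi", "degenerate")]
}

#' Mean SSI per vertical interval for one group
#'
#' For each vertical interval, averages the SSI values of the group's
#' species present there (sum of SSI divided by the number of present
#' species); intervals where no group member is present get \code{NA} and
#' are excluded from trend fits.
#'
#' @param niche_params Output of [ssi_per_region()] for the region.
#' @param pm The region's \code{presence_matrix}.
#' @param group One rooting-system group, or \code{"all"}.
#' @return Data frame \code{region_id, group, index, midpoint_m,
#'   n_species, mean_ssi}.
#' @export
mean_ssi_profile <- function(niche_params, pm, group) {
  stopifnot(inherits(pm, "presence_matrix"))
  rows <- if (group == "all") rep(TRUE, nrow(pm$matrix))
          else !is.na(pm$groups) & pm$groups == group
  taxa <- rownames(pm$matrix)[rows]
  ssi_of <- niche_params$ssi[match(taxa, niche_params$taxon_id)]
  if (anyNA(ssi_of)) {
    stop("species present in region ", pm$region_id,
         " but lacking SSI: ",
         paste(taxa[is.na(ssi_of)], collapse = ", "), call. = FALSE)
  }
  sub <- pm$matrix[rows, , drop = FALSE]
  n_sp <- colSums(sub)
  mean_ssi <- ifelse(n_sp > 0, colSums(sub * ssi_of) / n_sp, NA_real_)
  data.frame(
    region_id = pm$region_id,
    group = group,
    index = pm$intervals$index,
    midpoint_m = pm$intervals$midpoint_m,
    n_species = as.integer(n_sp),
    mean_ssi = mean_ssi,
    stringsAsFactors = FALSE
  )
}
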