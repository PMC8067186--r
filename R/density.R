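## Area-adjusted species density per vertical interval and mapping-grid
## occupancy summaries.

#' Area-adjusted species density
#'
#' Richness in a vertical interval adjusted for the interval's area:
#' \deqn{D = S / \log_{10}(A + 1)}
#' where \code{S} is the number of taxa recorded in the interval and
#' \code{A} its area in km2. The species-area convention of a base-10
#' logarithm is the default; natural log is available via \code{log_base}.
#'
#' @param S Taxon count(s), >= 0.
#' @param A Interval area(s) in km2, > 0.
#' @param log_base 10 (default) or \code{exp(1)}.
#' @return Density value(s), dimensionless.
#' @export
#' @examples
#' orchid_density(5, 9)    # log10(10) = 1  ->  5
#' orchid_density(12, 999) # log10(1000) = 3  ->  4
orchid_density <- function(S, A, log_base = 10) {
  if (any(!is.finite(A)) || any(A <= 0)) {
    stop("interval area A must be positive (area 0 has no defined density)",
         call. = FALSE)
  }
  if (any(S < 0)) stop("taxon count S must be nonnegative", call. = FALSE)
  S / log(A + 1, base = log_base)
}

#' Density profiles per group along the altitudinal gradient
#'
#' For each requested rooting-system group (plus the pooled \code{"all"}),
#' counts the taxa present in every vertical interval and converts the
#' counts to area-adjusted densities.
#'
#' @param pm A \code{presence_matrix} (one region).
#' @param groups Groups to profile; \code{"all"} pools every taxon.
#' @param log_base Passed to [orchid_density()].
#' @return Data frame \code{region_id, group, index, midpoint_m, S,
#'   area_km2, density}.
#' @export
density_profiles <- function(pm, groups = c("all", root_system_groups()),
                             log_base = 10) {
  stopifnot(inherits(pm, "presence_matrix"))
  unknown <- setdiff(groups, c("all", root_system_groups()))
  if (length(unknown)) {
    stop("unknown group(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  iv <- pm$intervals
  profiles <- lapply(groups, function(g) {
    rows <- if (g == "all") rep(TRUE, nrow(pm$matrix))
            else !is.na(pm$groups) & pm$groups == g
    S <- if (any(rows)) colSums(pm$matrix[rows, , drop = FALSE])
         else rep(0L, ncol(pm$matrix))
    data.frame(
      region_id = pm$region_id,
      group = g,
      index = iv$index,
      midpoint_m = iv$midpoint_m,
      S = as.integer(S),
      area_km2 = iv$area_km2,
      density = orchid_density(as.numeric(S), iv$area_km2, log_base),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, profiles)
  rownames(out) <- NULL
  out
}

#' Mapping-grid occupancy summary
#'
#' Counts the distinct coarse mapping-grid cells occupied by each
#' rooting-system group and by all taxa pooled, as a count and as a
#' percentage of the total mapping grid (rounded to 1 decimal, the usual
#' reporting precision of atlas studies).
#'
#' @param records Occurrence records carrying \code{mapping_cell_id}.
#' @param n_total Total number of mapping cells, or a \code{landscape_grid}
#'   from which to take it.
#' @return Data frame \code{group, occupied, total, percent}, with
#'   \code{"all"} first.
#' @export
#' @examples
#' occ <- data.frame(group = "rhizomatous", mapping_cell_id = c("a", "a", "b"))
#' occupancy_summary(occ, n_total = 10)
occupancy_summary <- function(records, n_total) {
  if (inherits(n_total, "landscape_grid")) n_total <- n_mapping_cells(n_total)
  if (is.na(n_total) || n_total <= 0) {
    stop("total number of mapping cells must be positive", call. = FALSE)
  }
  recs <- records[!is.na(records$mapping_cell_id), , drop = FALSE]
  count_cells <- function(rows) length(unique(recs$mapping_cell_id[rows]))
  groups <- root_system_groups()
  occupied <- c(count_cells(rep(TRUE, nrow(recs))),
                vapply(groups, function(g) count_cells(recs$group == g),
                       integer(1)))
  data.frame(
    group = c("all", groups),
    occupied = occupied,
    total = n_total,
    percent = round(100 * occupied / n_total, 1),
    stringsAsFactors = FALSE
  )
}
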