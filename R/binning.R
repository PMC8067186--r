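## 100-m vertical binning: altitude assignment from the grid, per-region
## interval tables with cell-count areas, and the binary presence matrix.

#' Assign altitude, cell and region to occurrence records
#'
#' Each record is matched to its nearest fine grid cell (Euclidean distance
#' in the x/y plane) and inherits that cell's altitude, region and mapping
#' cell. Altitude always comes from the grid, never from a record-supplied
#' column, so that presence accounting and interval areas use one layer.
#' Ties in distance go to the lexicographically smallest
#' \code{fine_cell_id}.
#'
#' @param records Occurrence data frame (needs \code{x}, \code{y}).
#' @param grid A \code{landscape_grid}.
#' @param max_dist Records farther than this from every cell center are
#'   dropped with a warning (or an error when \code{strict}).
#' @param strict Error instead of dropping out-of-grid records.
#' @return The records with \code{altitude_m}, \code{fine_cell_id},
#'   \code{region_id} and \code{mapping_cell_id} filled from the grid.
#' @export
assign_altitude <- function(records, grid, max_dist = Inf, strict = FALSE) {
  stopifnot(inherits(grid, "landscape_grid"))
  if (nrow(records) == 0) {
    for (col in c("altitude_m", "fine_cell_id", "region_id",
                  "mapping_cell_id")) {
      if (!col %in% names(records)) records[[col]] <- character(0)
    }
    return(records)
  }
  cells <- grid$cells
  ord <- order(cells$fine_cell_id) # lexicographic tie-break
  cells <- cells[ord, , drop = FALSE]

  nearest <- integer(nrow(records))
  dist2 <- numeric(nrow(records))
  chunk <- max(1L, floor(5e6 / nrow(cells)))
  for (start in seq(1L, nrow(records), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(records))
    d2 <- outer(records$x[rows], cells$x, "-")^2 +
      outer(records$y[rows], cells$y, "-")^2
    nearest[rows] <- max.col(-d2, ties.method = "first")
    dist2[rows] <- d2[cbind(seq_along(rows), nearest[rows])]
  }
  far <- sqrt(dist2) > max_dist
  if (any(far)) {
    msg <- paste0(sum(far), " record(s) farther than ", max_dist,
                  " from any grid cell")
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    records <- records[!far, , drop = FALSE]
    nearest <- nearest[!far]
  }
  records$altitude_m <- cells$altitude_m[nearest]
  records$fine_cell_id <- cells$fine_cell_id[nearest]
  records$region_id <- cells$region_id[nearest]
  records$mapping_cell_id <- cells$mapping_cell_id[nearest]
  rownames(records) <- NULL
  records
}

#' Index of the vertical interval containing an altitude
#'
#' Intervals are half-open bands \code{[width*k, width*(k+1))}; an altitude
#' exactly on a boundary belongs to the upper band.
#'
#' @param altitude_m Altitudes in meters.
#' @param width Interval width in meters (default 100).
#' @return Integer band indices \code{k = floor(altitude/width)}.
#' @export
interval_index <- function(altitude_m, width = 100) {
  stopifnot(width > 0)
  as.integer(floor(altitude_m / width))
}

#' Build the 100-m vertical interval table of a region
#'
#' One row per occupied altitude band of the region; the area of a band is
#' its fine-cell count times the cell area, so empty bands (area zero) are
#' never emitted.
#'
#' @param grid A \code{landscape_grid}.
#' @param region_id Region to tabulate.
#' @param width Interval width in meters.
#' @return Data frame with columns \code{region_id, index, lower_m,
#'   upper_m, midpoint_m, n_cells, area_km2}, ordered by index.
#' @export
build_intervals <- function(grid, region_id, width = 100) {
  stopifnot(inherits(grid, "landscape_grid"))
  in_region <- grid$cells$region_id == region_id
  if (!any(in_region)) {
    stop("unknown region: ", region_id, call. = FALSE)
  }
  k <- interval_index(grid$cells$altitude_m[in_region], width)
  counts <- table(k)
  idx <- as.integer(names(counts))
  ord <- order(idx)
  idx <- idx[ord]
  n_cells <- as.integer(counts)[ord]
  data.frame(
    region_id = region_id,
    index = idx,
    lower_m = idx * width,
    upper_m = (idx + 1) * width,
    midpoint_m = idx * width + width / 2,
    n_cells = n_cells,
    area_km2 = n_cells * grid$fine_cell_area_km2,
    stringsAsFactors = FALSE
  )
}

#' Binary presence matrix of taxa by vertical interval
#'
#' A taxon is present in an interval iff at least one of its records falls
#' in that altitude band of the region; duplicate records collapse to a
#' single presence.
#'
#' @param records Occurrence records annotated with \code{altitude_m} and
#'   \code{region_id} (see [assign_altitude()]).
#' @param intervals Interval table from [build_intervals()] (one region).
#' @param width Interval width in meters, matching \code{intervals}.
#' @return An object of class \code{presence_matrix}: a list with the 0/1
#'   \code{matrix} (taxa x intervals, dimnames taxon_id and interval
#'   index), \code{groups} (named by taxon), \code{region_id} and
#'   \code{intervals}.
#' @export
presence_matrix <- function(records, intervals, width = 100) {
  stopifnot(is.data.frame(intervals), nrow(intervals) > 0)
  region <- unique(intervals$region_id)
  stopifnot(length(region) == 1)
  recs <- records[!is.na(records$region_id) &
                    records$region_id == region, , drop = FALSE]
  taxa <- sort(unique(recs$taxon_id))
  mat <- matrix(0L, nrow = length(taxa), ncol = nrow(intervals),
                dimnames = list(taxa, as.character(intervals$index)))
  if (nrow(recs)) {
    k <- interval_index(recs$altitude_m, width)
    col <- match(as.character(k), colnames(mat))
    if (anyNA(col)) {
      stop("record(s) fall in altitude band(s) with no grid cells in ",
           region, ": ", paste(unique(k[is.na(col)]), collapse = ", "),
           call. = FALSE)
    }
    mat[cbind(match(recs$taxon_id, taxa), col)] <- 1L
  }
  groups <- stats::setNames(
    recs$group[match(taxa, recs$taxon_id)], taxa)
  structure(
    list(matrix = mat, groups = groups, region_id = region,
         intervals = intervals),
    class = "presence_matrix"
  )
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("Presence matrix for region", x$region_id, ":",
      nrow(x$matrix), "taxa x", ncol(x$matrix), "vertical intervals;",
      sum(x$matrix), "presences\n")
  invisible(x)
}

#' Presence matrix in long format
#'
#' @param pm A \code{presence_matrix}.
#' @return Data frame \code{region_id, taxon_id, group, index, presence}.
#' @export
presence_long <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  if (nrow(pm$matrix) == 0) {
    return(data.frame(region_id = character(0), taxon_id = character(0),
                      group = character(0), index = integer(0),
                      presence = integer(0)))
  }
  out <- expand.grid(taxon_id = rownames(pm$matrix),
                     index = as.integer(colnames(pm$matrix)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$region_id <- pm$region_id
  out$group <- unname(pm$groups[out$taxon_id])
  out$presence <- as.integer(pm$matrix[cbind(
    match(out$taxon_id, rownames(pm$matrix)),
    match(as.character(out$index), colnames(pm$matrix)))])
  out[c("region_id", "taxon_id", "group", "index", "presence")]
}
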