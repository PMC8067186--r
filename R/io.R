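## Readers and writers for the two tabular inputs (occurrence records and
## the landscape grid). Everything is plain UTF-8 CSV with a header row.

occurrence_columns <- c("taxon_id", "genus", "group", "x", "y", "region_id",
                        "altitude_m", "fine_cell_id", "mapping_cell_id")

#' Read occurrence records from CSV
#'
#' Required columns: \code{taxon_id, genus, x, y}. Optional columns
#' (\code{region_id, altitude_m, fine_cell_id, mapping_cell_id}) are kept
#' when present and created as \code{NA} otherwise. Each record is annotated
#' with its rooting-system group via the lookup.
#'
#' @param path CSV file path.
#' @param lookup Genus lookup, see [root_system_lookup()].
#' @param strict If \code{TRUE}, unknown genera and malformed rows are
#'   errors; otherwise they are dropped with a warning naming the data rows.
#' @return Data frame of occurrence records (one row per record).
#' @export
read_occurrences <- function(path, lookup = root_system_lookup(),
                             strict = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("taxon_id", "genus", "x", "y")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("occurrence file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(occurrence_columns, names(raw))) {
    raw[[col]] <- rep(NA, nrow(raw))
  }
  raw <- raw[occurrence_columns]
  raw$x <- suppressWarnings(as.numeric(raw$x))
  raw$y <- suppressWarnings(as.numeric(raw$y))

  bad <- which(!is.finite(raw$x) | !is.finite(raw$y) |
                 is.na(raw$taxon_id) | !nzchar(raw$taxon_id) |
                 is.na(raw$genus) | !nzchar(raw$genus))
  if (length(bad)) {
    msg <- paste0("malformed occurrence row(s) at data line(s): ",
                  paste(bad, collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    raw <- raw[-bad, , drop = FALSE]
  }

  known <- raw$genus %in% lookup$genus
  if (!all(known)) {
    unknown <- unique(raw$genus[!known])
    if (strict) {
      classify_root_system(unknown, lookup) # raises unclassified error
    }
    warning("skipping ", sum(!known), " record(s) with unclassified ",
            "genus: ", paste(unknown, collapse = ", "), call. = FALSE)
    raw <- raw[known, , drop = FALSE]
  }
  raw$group <- if (nrow(raw)) classify_root_system(raw$genus, lookup)
               else character(0)
  rownames(raw) <- NULL
  raw
}

#' @rdname read_occurrences
#' @param occ Occurrence data frame to write.
#' @export
write_occurrences <- function(occ, path) {
  for (col in setdiff(occurrence_columns, names(occ))) occ[[col]] <- NA
  utils::write.csv(occ[occurrence_columns], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a landscape grid object
#'
#' The grid is the fine-resolution altitude layer: one row per cell with
#' planar coordinates, altitude in meters, a region label, zero or more
#' environmental covariates (columns named \code{env_*}), and optionally a
#' coarser mapping-grid cell id used for occupancy summaries.
#'
#' @param cells Data frame with columns \code{fine_cell_id, x, y,
#'   altitude_m, region_id}, optional \code{mapping_cell_id}, and any number
#'   of \code{env_} covariate columns.
#' @param fine_cell_area_km2 Area of one fine cell in km2.
#' @return An object of class \code{landscape_grid}: a list with elements
#'   \code{cells}, \code{fine_cell_area_km2} and \code{env_vars}.
#' @export
landscape_grid <- function(cells, fine_cell_area_km2 = 1) {
  stopifnot(is.data.frame(cells))
  required <- c("fine_cell_id", "x", "y", "altitude_m", "region_id")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols)) {
    stop("grid lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cells$fine_cell_id <- as.character(cells$fine_cell_id)
  if (anyDuplicated(cells$fine_cell_id)) {
    stop("duplicated fine_cell_id in grid: ",
         paste(unique(cells$fine_cell_id[duplicated(cells$fine_cell_id)]),
               collapse = ", "), call. = FALSE)
  }
  env_vars <- grep("^env_", names(cells), value = TRUE)
  num_cols <- c("x", "y", "altitude_m", env_vars)
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(cells[[col]]))
    if (any(!is.finite(v))) {
      stop("non-finite ", col, " for cell(s): ",
           paste(cells$fine_cell_id[!is.finite(v)], collapse = ", "),
           call. = FALSE)
    }
    cells[[col]] <- v
  }
  if (!is.finite(fine_cell_area_km2) || fine_cell_area_km2 <= 0) {
    stop("fine_cell_area_km2 must be a positive number", call. = FALSE)
  }
  if (!"mapping_cell_id" %in% names(cells)) cells$mapping_cell_id <- NA
  rownames(cells) <- NULL
  structure(
    list(cells = cells, fine_cell_area_km2 = fine_cell_area_km2,
         env_vars = env_vars),
    class = "landscape_grid"
  )
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat("Landscape grid:", nrow(x$cells), "cells,",
      length(unique(x$cells$region_id)), "region(s),",
      length(x$env_vars), "environmental covariate(s)\n")
  cat("  altitude:", round(min(x$cells$altitude_m)), "-",
      round(max(x$cells$altitude_m)), "m;  cell area:",
      x$fine_cell_area_km2, "km2\n")
  nm <- n_mapping_cells(x)
  if (!is.na(nm)) cat("  mapping grid:", nm, "cells\n")
  invisible(x)
}

#' Number of distinct mapping-grid cells of a landscape grid
#'
#' @param grid A \code{landscape_grid}.
#' @return Integer count, or \code{NA} when no mapping grid is assigned.
#' @export
n_mapping_cells <- function(grid) {
  ids <- grid$cells$mapping_cell_id
  if (all(is.na(ids))) NA_integer_ else length(unique(ids[!is.na(ids)]))
}

#' Read / write a landscape grid CSV
#'
#' @param path CSV path with columns \code{fine_cell_id, x, y, altitude_m,
#'   region_id}, optional \code{mapping_cell_id} and \code{env_*} columns.
#' @param fine_cell_area_km2 Cell area in km2 (a property of the layer, not
#'   stored per row).
#' @return [read_grid()] returns a \code{landscape_grid};
#'   [write_grid()] returns the path invisibly.
#' @export
read_grid <- function(path, fine_cell_area_km2 = 1) {
  landscape_grid(utils::read.csv(path, stringsAsFactors = FALSE),
                 fine_cell_area_km2 = fine_cell_area_km2)
}

#' @rdname read_grid
#' @param grid A \code{landscape_grid} object.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "landscape_grid"))
  utils::write.csv(grid$cells, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Assign mapping-grid cells by coordinate
#'
#' Occupancy summaries use a coarser national-atlas style grid. When the
#' input does not carry a \code{mapping_cell_id} column this derives one by
#' snapping coordinates to a square grid of the given cell size.
#'
#' @param grid A \code{landscape_grid}.
#' @param cell_size Side length of a mapping cell, in the units of
#'   \code{x}/\code{y}.
#' @return The grid with \code{mapping_cell_id} filled.
#' @export
assign_mapping_cells <- function(grid, cell_size) {
  stopifnot(inherits(grid, "landscape_grid"), cell_size > 0)
  cx <- floor(grid$cells$x / cell_size)
  cy <- floor(grid$cells$y / cell_size)
  grid$cells$mapping_cell_id <- sprintf("M_%d_%d", cx, cy)
  grid
}
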