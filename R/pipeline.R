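## File-based pipeline driver: config -> (simulate|read) -> analyse ->
## write CSV outputs + a run manifest with checksums, and a Markdown report.

#' Pipeline configuration
#'
#' Bundles every knob of the analysis with the study defaults: 100-m
#' intervals, base-10 area logarithm, alpha = 0.05 degree selection,
#' occupied-site niche decomposition and per-region Tmax. Inputs are either
#' file paths (\code{grid_path} + \code{occurrences_path}) or a
#' [simulation_config()] under \code{sim}.
#'
#' @param out_dir Output directory (created if needed).
#' @param grid_path,occurrences_path CSV inputs, see [read_grid()] and
#'   [read_occurrences()].
#' @param sim A \code{sim_config}; used when file paths are absent.
#' @param regions,groups,alpha,log_base,interval_width,sites,tmax_scope
#'   Passed to [alti_gradient()].
#' @param fine_cell_area_km2 Cell area used when reading a grid from file.
#' @param rng_seed Seed controlling any simulation.
#' @return A validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir,
                            grid_path = NULL,
                            occurrences_path = NULL,
                            sim = NULL,
                            regions = NULL,
                            groups = root_system_groups(),
                            alpha = 0.05,
                            log_base = 10,
                            interval_width = 100,
                            sites = "occupied",
                            tmax_scope = "region",
                            fine_cell_area_km2 = 1,
                            rng_seed = 1L) {
  if (interval_width <= 0) stop("interval_width must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  from_files <- !is.null(grid_path) || !is.null(occurrences_path)
  if (from_files) {
    if (is.null(grid_path) || !file.exists(grid_path)) {
      stop("grid_path missing or not found: ",
           if (is.null(grid_path)) "<unset>" else grid_path, call. = FALSE)
    }
    if (is.null(occurrences_path) || !file.exists(occurrences_path)) {
      stop("occurrences_path missing or not found: ",
           if (is.null(occurrences_path)) "<unset>" else occurrences_path,
           call. = FALSE)
    }
  } else if (is.null(sim)) {
    sim <- simulation_config(rng_seed = rng_seed)
  }
  structure(
    list(out_dir = out_dir, grid_path = grid_path,
         occurrences_path = occurrences_path, sim = sim,
         regions = regions, groups = groups, alpha = alpha,
         log_base = log_base, interval_width = interval_width,
         sites = sites, tmax_scope = tmax_scope,
         fine_cell_area_km2 = fine_cell_area_km2,
         rng_seed = as.integer(rng_seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; an optional
#' \code{sim:} mapping is passed to [simulation_config()].
#'
#' @param path YAML file.
#' @param ... Overrides applied on top of the file's values.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path, ...) {
  spec <- yaml::read_yaml(path)
  overrides <- list(...)
  spec[names(overrides)] <- overrides
  if (!is.null(spec$sim) && !inherits(spec$sim, "sim_config")) {
    spec$sim <- do.call(simulation_config, spec$sim)
  }
  do.call(pipeline_config, spec)
}

pipeline_files <- c(grid = "grid.csv", occurrences = "occurrences.csv",
                    ground_truth = "ground_truth.csv",
                    intervals = "intervals.csv", presence = "presence.csv",
                    density = "density.csv",
                    niche_params = "niche_params.csv",
                    ssi_profiles = "ssi_profiles.csv",
                    occupancy = "occupancy.csv", trends = "trends.csv")

#' Run the full pipeline
#'
#' Simulates (or reads) the inputs, runs [alti_gradient()], writes every
#' stage's table as CSV under the output directory, and returns a manifest
#' recording the effective configuration and an md5 checksum per file. Two
#' runs with the same configuration and seed produce byte-identical files.
#'
#' @param config A [pipeline_config()] (or a YAML path understood by
#'   [read_pipeline_config()]).
#' @return Invisibly, the manifest: list with \code{files} (named paths),
#'   \code{checksums}, \code{config} and the fitted \code{alti_gradient}
#'   under \code{fit}. Class \code{altiniche_manifest}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir, pipeline_files)
  names(paths) <- names(pipeline_files)

  ground_truth <- NULL
  if (!is.null(config$grid_path)) {
    grid <- read_grid(config$grid_path,
                      fine_cell_area_km2 = config$fine_cell_area_km2)
    occ <- read_occurrences(config$occurrences_path)
  } else {
    study <- simulate_study(config$sim)
    grid <- study$grid
    occ <- study$occurrences
    ground_truth <- study$pool
  }
  write_grid(grid, paths["grid"])
  write_occurrences(occ, paths["occurrences"])
  if (!is.null(ground_truth)) {
    write_csv_utf8(ground_truth, paths["ground_truth"])
  }

  fit <- alti_gradient(occ, grid,
                       regions = config$regions, groups = config$groups,
                       alpha = config$alpha, log_base = config$log_base,
                       interval_width = config$interval_width,
                       sites = config$sites,
                       tmax_scope = config$tmax_scope)

  write_csv_utf8(fit$intervals, paths["intervals"])
  write_csv_utf8(fit$presence, paths["presence"])
  write_csv_utf8(fit$density, paths["density"])
  write_csv_utf8(fit$niche, paths["niche_params"])
  write_csv_utf8(fit$ssi_profiles, paths["ssi_profiles"])
  trends_out <- fit$trends
  trends_out$r_squared <- round(trends_out$r_squared, 2)
  write_csv_utf8(trends_out, paths["trends"])
  if (!is.null(fit$occupancy)) {
    write_csv_utf8(fit$occupancy, paths["occupancy"])
  } else {
    paths <- paths[names(paths) != "occupancy"]
  }
  if (is.null(ground_truth)) paths <- paths[names(paths) != "ground_truth"]

  manifest <- structure(
    list(files = paths,
         checksums = tools::md5sum(paths),
         config = config,
         fit = fit),
    class = "altiniche_manifest"
  )
  invisible(manifest)
}

write_csv_utf8 <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' @export
print.altiniche_manifest <- function(x, ...) {
  cat("Pipeline run:", length(x$files), "output files in",
      x$config$out_dir, "\n")
  for (nm in names(x$files)) {
    cat(sprintf("  %-13s %s  %s\n", nm, unname(x$checksums[nm]),
                basename(x$files[nm])))
  }
  invisible(x)
}

#' Render a Markdown report of a pipeline run
#'
#' Produces the study-style summary: the mapping-grid occupancy sentence,
#' a density-trend table and a mean-SSI trend table (one row per region and
#' group with R2, degree label a/b/c and significance).
#'
#' @param manifest An \code{altiniche_manifest} from [run_pipeline()].
#' @param path Optional file to write; the Markdown lines are returned
#'   either way.
#' @return Character vector of Markdown lines, invisibly when written.
#' @export
render_report <- function(manifest, path = NULL) {
  stopifnot(inherits(manifest, "altiniche_manifest"))
  fit <- manifest$fit
  missing_stages <- setdiff(c("intervals", "density", "niche", "trends"),
                            names(fit)[!vapply(fit, is.null, logical(1))])
  if (length(missing_stages) || nrow(fit$trends) == 0) {
    stop("incomplete run; missing stage(s): ",
         paste(c(missing_stages,
                 if (nrow(fit$trends) == 0) "trends"), collapse = ", "),
         call. = FALSE)
  }
  lines <- c("# Altitudinal gradient analysis report", "")
  if (!is.null(fit$occupancy)) {
    occ <- fit$occupancy
    all_row <- occ[occ$group == "all", ]
    lines <- c(lines, "## Mapping-grid occupancy", "",
               sprintf(paste0("Taxa were recorded in %d (%.1f%%) of the ",
                              "%d mapping-grid cells."),
                       all_row$occupied, all_row$percent, all_row$total),
               "",
               md_table(occ), "")
  }
  trend_block <- function(resp, title) {
    tr <- fit$trends[fit$trends$response == resp, , drop = FALSE]
    if (!nrow(tr)) return(character(0))
    tr <- data.frame(region = tr$region_id, group = tr$group,
                     `R2` = sprintf("%.2f", tr$r_squared),
                     degree = tr$degree_label,
                     significance = tr$significance_label,
                     check.names = FALSE)
    c(paste("##", title), "", md_table(tr), "",
      paste("(a): 1st, (b): 2nd, (c): 3rd order polynomial;",
            "ns: not significant."), "")
  }
  lines <- c(lines,
             trend_block("density", "Area-adjusted density trends"),
             trend_block("mean_ssi", "Mean SSI trends"))
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

md_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE),
                  character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
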