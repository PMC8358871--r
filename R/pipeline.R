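# End-to-end orchestration: simulate -> measure -> stats, with config,
# deterministic outputs, and exclusion logging.

pipeline_config_keys <- c(
  "seed", "cohort", "params", "tile_px", "min_areas",
  "threshold_method", "fixed_nephrin", "fixed_cldn5",
  "z_min", "z_max", "prune_px", "ratio_up", "continuity_max", "contrasts"
)

#' Pipeline configuration
#'
#' Validated configuration for [run_end_to_end()]. Unknown keys are
#' rejected. The full configuration is serialized into every run's log.
#'
#' @param seed master seed for the synthetic cohort.
#' @param cohort cohort specification as in [generate_cohort()]; defaults
#'   to [default_cohort_spec()].
#' @param params a [synth_params()] template for every sample.
#' @param tile_px edge length (pixels) of the auto-tiled square ROIs laid
#'   over each field's evaluable region.
#' @param min_areas minimum valid areas per glomerulus (default 20).
#' @param threshold_method,fixed_nephrin,fixed_cldn5,z_min,z_max,prune_px
#'   passed to [measure_config()].
#' @param ratio_up,continuity_max passed to [phase_thresholds()].
#' @param contrasts list of group contrasts for [cohort_analysis()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = default_cohort_spec(),
                            params = synth_params(),
                            tile_px = 24L,
                            min_areas = 20L,
                            threshold_method = "otsu",
                            fixed_nephrin = NULL,
                            fixed_cldn5 = NULL,
                            z_min = NULL,
                            z_max = NULL,
                            prune_px = 3L,
                            ratio_up = 0.5,
                            continuity_max = 0.1,
                            contrasts = list("control:MCD", "control:FSGS",
                                             "control:MCD+FSGS")) {
  stop_if_not_scalar_number(seed, "seed", min = -2^31, max = 2^31)
  stop_if_not_scalar_number(tile_px, "tile_px", min = 4)
  stop_if_not_scalar_number(min_areas, "min_areas", min = 1)
  if (!inherits(params, "synth_params")) {
    stop("`params` must be a synth_params() object", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), cohort = cohort, params = params,
                 tile_px = as.integer(tile_px),
                 min_areas = as.integer(min_areas),
                 threshold_method = threshold_method,
                 fixed_nephrin = fixed_nephrin, fixed_cldn5 = fixed_cldn5,
                 z_min = z_min, z_max = z_max, prune_px = as.integer(prune_px),
                 ratio_up = ratio_up, continuity_max = continuity_max,
                 contrasts = contrasts),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected (schema validation). Nested `params` entries
#' are passed to [synth_params()], `cohort` entries to [generate_cohort()].
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  doc <- yaml::read_yaml(path)
  unknown <- setdiff(names(doc), pipeline_config_keys)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(doc$params)) doc$params <- do.call(synth_params, doc$params)
  do.call(pipeline_config, doc)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$params <- unclass(out$params)
  out
}

measure_config_from <- function(config) {
  measure_config(threshold_method = config$threshold_method,
                 fixed_nephrin = config$fixed_nephrin,
                 fixed_cldn5 = config$fixed_cldn5,
                 z_min = config$z_min, z_max = config$z_max,
                 prune_px = config$prune_px,
                 thresholds = phase_thresholds(config$ratio_up,
                                               config$continuity_max))
}

#' Tile an evaluable region into square ROIs
#'
#' Lays a grid of `tile_px`-sized square ROIs over the axis-aligned
#' bounding box of a parent ROI, keeping tiles fully inside it. This is the
#' synthetic stand-in for manual selection of plan filtration-slit areas.
#'
#' @param roi parent [slit_roi()] (typically the generator's full
#'   evaluable region).
#' @param tile_px tile edge length in pixels.
#' @param glomerulus_id label for the tiles; defaults to the parent's.
#' @return list of [slit_roi()] tiles.
#' @export
tile_rois <- function(roi, tile_px = 24L, glomerulus_id = NULL) {
  v <- roi$vertices
  gid <- glomerulus_id %||% roi$glomerulus_id
  x0 <- min(v[, 1]); x1 <- max(v[, 1])
  y0 <- min(v[, 2]); y1 <- max(v[, 2])
  nx <- floor((x1 - x0) / tile_px)
  ny <- floor((y1 - y0) / tile_px)
  if (nx < 1L || ny < 1L) stop("parent ROI smaller than one tile", call. = FALSE)
  # center the grid inside the parent box
  ox <- x0 + ((x1 - x0) - nx * tile_px) / 2
  oy <- y0 + ((y1 - y0) - ny * tile_px) / 2
  tiles <- list()
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      tx0 <- ox + (ix - 1L) * tile_px
      ty0 <- oy + (iy - 1L) * tile_px
      tiles[[length(tiles) + 1L]] <- slit_roi(
        cbind(c(tx0, tx0 + tile_px, tx0 + tile_px, tx0),
              c(ty0, ty0, ty0 + tile_px, ty0 + tile_px)),
        roi_id = sprintf("%s_tile_%02d_%02d", gid, iy, ix),
        glomerulus_id = gid,
        pixel_size_um = roi$pixel_size_um)
    }
  }
  tiles
}

#' Measure a synthetic cohort in memory
#'
#' Shared compute path of [run_end_to_end()]: generates the cohort, tiles
#' each sample's evaluable region, measures every tile, summarizes
#' glomeruli, and builds the per-sample cohort table.
#'
#' @param config a [pipeline_config()].
#' @return list with `samples` (generator output), `measurements`,
#'   `summaries`, `excluded`, `cohort_table`, `report`.
#' @export
run_cohort_analysis <- function(config = pipeline_config()) {
  mcfg <- measure_config_from(config)
  samples <- generate_cohort(config$cohort, seed = config$seed,
                             params = config$params)
  measurements <- list()
  for (s in samples) {
    tiles <- tile_rois(s$roi, tile_px = config$tile_px,
                       glomerulus_id = s$sample_id)
    measurements[[length(measurements) + 1L]] <-
      measure_sample(s$stack, tiles, config = mcfg, sample_id = s$sample_id)
  }
  measurements <- do.call(rbind, measurements)
  agg <- summarize_glomeruli(measurements, min_areas = config$min_areas)
  # per-sample averages of glomerular means (here: one glomerulus per sample)
  labels <- stats::setNames(vapply(samples, `[[`, character(1), "label"),
                            vapply(samples, `[[`, character(1), "sample_id"))
  cohort_table <- NULL
  if (nrow(agg$summaries) > 0L) {
    sp <- split(agg$summaries, agg$summaries$sample_id)
    cohort_table <- do.call(rbind, lapply(sp, function(d) {
      data.frame(sample_id = d$sample_id[1],
                 group = unname(labels[d$sample_id[1]]),
                 mean_ratio = mean(d$mean_ratio),
                 mean_fsd_per_um = mean(d$mean_fsd_per_um),
                 stringsAsFactors = FALSE)
    }))
    cohort_table <- cohort_table[order(match(cohort_table$sample_id,
                                             names(labels))), , drop = FALSE]
    rownames(cohort_table) <- NULL
  }
  report <- if (!is.null(cohort_table) && nrow(cohort_table) >= 3L) {
    usable <- Filter(function(ct) {
      all(unlist(parse_contrast(ct)) %in% cohort_table$group)
    }, config$contrasts)
    cohort_analysis(cohort_table, contrasts = usable)
  } else {
    NULL
  }
  list(samples = samples, measurements = measurements,
       summaries = agg$summaries, excluded = agg$excluded,
       cohort_table = cohort_table, report = report)
}

#' Run the full pipeline into a directory
#'
#' Simulates the cohort, writes every stack (TIFF + metadata sidecar), ROI
#' file, and ground truth, measures all tiled areas, writes measurement and
#' summary CSVs, the cohort table, the statistics report, and a run log
#' (config, seeds, versions, per-glomerulus exclusions). Outputs are
#' deterministic: re-running the same configuration reproduces byte-identical
#' CSV/JSON files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; must be empty or absent).
#' @return the output directory, invisibly; side effect: files under
#'   `out_dir` (`stacks/`, `rois/`, `truth/`, `measurements.csv`,
#'   `summaries.csv`, `cohort.csv`, `report.json`, `log.json`).
#' @export
run_end_to_end <- function(config = pipeline_config(), out_dir) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L) {
    stop("output directory exists and is not empty: ", out_dir, call. = FALSE)
  }
  for (d in c("", "stacks", "rois", "truth")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  res <- run_cohort_analysis(config)
  for (s in res$samples) {
    write_stack(s$stack, file.path(out_dir, "stacks",
                                   paste0(s$sample_id, ".tif")))
    tiles <- tile_rois(s$roi, tile_px = config$tile_px,
                       glomerulus_id = s$sample_id)
    write_rois(tiles, file.path(out_dir, "rois",
                                paste0(s$sample_id, ".json")))
    tr <- s$truth
    jsonlite::write_json(
      list(sample_id = s$sample_id, label = s$label,
           effacement = s$effacement,
           total_slit_length_um = tr$total_slit_length_um,
           roi_area_um2 = tr$roi_area_um2,
           cldn5_covered_length_um = tr$cldn5_covered_length_um,
           true_fsd_per_um = tr$true_fsd_per_um,
           true_coverage = tr$true_coverage),
      file.path(out_dir, "truth", paste0(s$sample_id, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  write_measurements(res$measurements, file.path(out_dir, "measurements.csv"))
  write_measurements(res$summaries, file.path(out_dir, "summaries.csv"))
  if (!is.null(res$cohort_table)) {
    utils::write.csv(res$cohort_table, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$report)) {
    write_report(res$report, file.path(out_dir, "report.json"),
                 file.path(out_dir, "contrasts.csv"))
  }
  log <- list(
    package_version = as.character(utils::packageVersion("slitmorph")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config_as_list(config),
    n_samples = length(res$samples),
    excluded_glomeruli = res$excluded
  )
  jsonlite::write_json(log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
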