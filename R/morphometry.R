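# Per-ROI morphometry: CLDN5/nephrin area ratio, filtration slit density,
# continuity, and effacement-phase classification.

#' CLDN5/nephrin positive-area ratio within an ROI
#'
#' Claudin-5-positive area divided by nephrin-positive area, both counted
#' inside the ROI. A nephrin-negative ROI (possible in severe effacement)
#' yields `NA` — a flagged-invalid result that summaries exclude — rather
#' than an error. Ratios above 1 are legitimate and indicate
#' claudin-5-positive but nephrin-negative slit segments.
#'
#' @param cldn5_mask,nephrin_mask `binary_mask` objects sharing geometry.
#' @param roi a [slit_roi()].
#' @return dimensionless ratio, or `NA` if the nephrin area is zero.
#' @export
cldn5_nephrin_ratio <- function(cldn5_mask, nephrin_mask, roi) {
  if (!identical(dim(cldn5_mask$grid), dim(nephrin_mask$grid))) {
    stop("masks must share geometry", call. = FALSE)
  }
  a_n <- positive_area(nephrin_mask, roi)
  a_c <- positive_area(cldn5_mask, roi)
  if (a_n <= 0) return(NA_real_)
  a_c / a_n
}

#' Filtration slit density
#'
#' FSD = l_FS / A: total nephrin-positive slit length divided by the area
#' of the evaluable region, in 1/um.
#'
#' @param l_fs_um slit length in um.
#' @param roi_area_um2 evaluable area in um^2 (> 0).
#' @return FSD in 1/um.
#' @examples
#' filtration_slit_density(50, 25)
#' @export
filtration_slit_density <- function(l_fs_um, roi_area_um2) {
  if (!is.finite(roi_area_um2) || roi_area_um2 <= 0) {
    stop("ROI area must be positive", call. = FALSE)
  }
  l_fs_um / roi_area_um2
}

#' Thresholds for effacement-phase classification
#'
#' Defaults are package choices: the study phases are described
#' qualitatively (phase 1: claudin-5 up-regulation along continuous
#' nephrin; phase 2: discontinuous nephrin with claudin-5-positive,
#' nephrin-negative segments).
#'
#' @param ratio_up CLDN5/nephrin ratio at or above which claudin-5 counts
#'   as up-regulated (default 0.5).
#' @param continuity_max maximum nephrin gaps per um still regarded as
#'   continuous (default 0.1).
#' @return list of class `phase_thresholds`.
#' @export
phase_thresholds <- function(ratio_up = 0.5, continuity_max = 0.1) {
  stop_if_not_scalar_number(ratio_up, "ratio_up", min = 0)
  stop_if_not_scalar_number(continuity_max, "continuity_max", min = 0)
  structure(list(ratio_up = ratio_up, continuity_max = continuity_max),
            class = "phase_thresholds")
}

#' Classify the effacement phase of a measurement
#'
#' Rule-based: `phase2` if the nephrin continuity index exceeds
#' `continuity_max` (discontinuous nephrin); else `phase1` if the
#' CLDN5/nephrin ratio reaches `ratio_up` (claudin-5 up-regulated along
#' continuous nephrin); else `healthy`. Flagged-invalid measurements are
#' unclassifiable (`NA`).
#'
#' @param ratio CLDN5/nephrin area ratio (or a one-row [measure_area()]
#'   record, in which case `gaps_per_um` is taken from it).
#' @param gaps_per_um continuity index from [continuity_index()].
#' @param thresholds a [phase_thresholds()] object.
#' @return one of `"healthy"`, `"phase1"`, `"phase2"`, or `NA`.
#' @export
classify_phase <- function(ratio, gaps_per_um = NULL,
                           thresholds = phase_thresholds()) {
  if (is.data.frame(ratio)) {
    gaps_per_um <- ratio$continuity_gaps_per_um
    ratio <- ratio$ratio
  }
  if (is.na(ratio) || is.na(gaps_per_um)) return(NA_character_)
  if (gaps_per_um > thresholds$continuity_max) return("phase2")
  if (ratio >= thresholds$ratio_up) return("phase1")
  "healthy"
}

#' Measurement configuration
#'
#' Thresholding, projection, skeleton, and classification settings used by
#' [measure_area()].
#'
#' @param threshold_method `"otsu"` (ROI-restricted histogram, the default)
#'   or `"fixed"`.
#' @param fixed_nephrin,fixed_cldn5 fixed thresholds, required when
#'   `threshold_method = "fixed"`.
#' @param z_min,z_max optional projection z window (1-based, inclusive).
#' @param prune_px skeleton spur-prune length in pixels.
#' @param thresholds a [phase_thresholds()] object.
#' @return list of class `measure_config`.
#' @export
measure_config <- function(threshold_method = c("otsu", "fixed"),
                           fixed_nephrin = NULL, fixed_cldn5 = NULL,
                           z_min = NULL, z_max = NULL, prune_px = 3L,
                           thresholds = phase_thresholds()) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" &&
      (is.null(fixed_nephrin) || is.null(fixed_cldn5))) {
    stop("fixed thresholds require `fixed_nephrin` and `fixed_cldn5`",
         call. = FALSE)
  }
  structure(list(threshold_method = threshold_method,
                 fixed_nephrin = fixed_nephrin, fixed_cldn5 = fixed_cldn5,
                 z_min = z_min, z_max = z_max,
                 prune_px = as.integer(prune_px),
                 thresholds = thresholds),
            class = "measure_config")
}

#' Measure one filtration-slit area
#'
#' Full per-ROI measurement: maximum intensity projection of each channel,
#' per-channel binarization (Otsu on the ROI-restricted histogram by
#' default), CLDN5/nephrin area ratio, nephrin skeletonization, slit
#' length, FSD, the boundary-aware gap density ([slit_gap_density()],
#' reported as `continuity_gaps_per_um`), and phase classification.
#' Thresholds used are recorded in the output for provenance. A
#' nephrin-negative ROI yields a flagged (`valid = FALSE`) record.
#'
#' @param stack a [channel_stack()] with `nephrin` and `cldn5` channels.
#' @param roi a [slit_roi()].
#' @param config a [measure_config()].
#' @param sample_id sample label recorded in the output.
#' @return one-row data.frame with columns `sample_id`, `glomerulus_id`,
#'   `roi_id`, `nephrin_area_um2`, `cldn5_area_um2`, `ratio`, `l_fs_um`,
#'   `roi_area_um2`, `fsd_per_um`, `phase`, `continuity_gaps_per_um`,
#'   `nephrin_threshold`, `cldn5_threshold`, `valid`.
#' @export
measure_area <- function(stack, roi, config = measure_config(),
                         sample_id = NA_character_) {
  stopifnot(inherits(stack, "channel_stack"), inherits(roi, "slit_roi"))
  for (ch in c("nephrin", "cldn5")) {
    if (!ch %in% names(stack$channels)) {
      stop("stack lacks required channel: ", ch, call. = FALSE)
    }
  }
  mip_n <- max_intensity_projection(stack, "nephrin", config$z_min, config$z_max)
  mip_c <- max_intensity_projection(stack, "cldn5", config$z_min, config$z_max)
  if (config$threshold_method == "fixed") {
    mask_n <- binarize(mip_n, "fixed", fixed_threshold = config$fixed_nephrin,
                       channel_name = "nephrin")
    mask_c <- binarize(mip_c, "fixed", fixed_threshold = config$fixed_cldn5,
                       channel_name = "cldn5")
  } else {
    mask_n <- binarize(mip_n, "otsu", roi = roi, channel_name = "nephrin")
    mask_c <- binarize(mip_c, "otsu", roi = roi, channel_name = "cldn5")
  }

  area_n <- positive_area(mask_n, roi)
  area_c <- positive_area(mask_c, roi)
  ratio <- if (area_n > 0) area_c / area_n else NA_real_

  skel <- skeletonize_slits(mask_n, roi = roi, prune_px = config$prune_px)
  l_fs <- skeleton_length(skel)
  a_roi <- roi_area_um2(roi)
  fsd <- filtration_slit_density(l_fs, a_roi)
  # boundary-aware gap measure: slits crossing the ROI edge are not gaps
  gaps <- slit_gap_density(skel, roi)

  valid <- is.finite(ratio)
  phase <- if (valid) {
    classify_phase(ratio, if (is.finite(gaps)) gaps else Inf,
                   config$thresholds)
  } else {
    NA_character_
  }

  data.frame(sample_id = sample_id,
             glomerulus_id = roi$glomerulus_id,
             roi_id = roi$roi_id,
             nephrin_area_um2 = area_n,
             cldn5_area_um2 = area_c,
             ratio = ratio,
             l_fs_um = l_fs,
             roi_area_um2 = a_roi,
             fsd_per_um = fsd,
             phase = if (is.null(phase) || length(phase) == 0) NA_character_ else phase,
             continuity_gaps_per_um = gaps,
             nephrin_threshold = mask_n$threshold_used,
             cldn5_threshold = mask_c$threshold_used,
             valid = valid,
             stringsAsFactors = FALSE)
}

#' Measure every ROI of a sample
#'
#' @param stack a [channel_stack()].
#' @param rois list of [slit_roi()] objects.
#' @inheritParams measure_area
#' @return data.frame, one row per ROI.
#' @export
measure_sample <- function(stack, rois, config = measure_config(),
                           sample_id = NA_character_) {
  do.call(rbind, lapply(rois, measure_area, stack = stack, config = config,
                        sample_id = sample_id))
}

#' Summarize a glomerulus over its measured areas
#'
#' Arithmetic mean of ratio and FSD over valid records. Glomeruli with
#' fewer than `min_areas` valid areas carry too little support and are
#' rejected with an exclusion error naming the glomerulus (condition class
#' `slitmorph_exclusion`).
#'
#' @param records data.frame of [measure_area()] rows sharing one
#'   `glomerulus_id`.
#' @param min_areas minimum number of valid areas (default 20).
#' @return one-row data.frame: `sample_id`, `glomerulus_id`, `n_areas`,
#'   `mean_ratio`, `mean_fsd_per_um`.
#' @export
summarize_glomerulus <- function(records, min_areas = 20L) {
  gid <- unique(records$glomerulus_id)
  if (length(gid) != 1L) {
    stop("records must share a single glomerulus_id", call. = FALSE)
  }
  valid <- records[records$valid %in% TRUE, , drop = FALSE]
  if (nrow(valid) < min_areas) {
    stop(structure(class = c("slitmorph_exclusion", "error", "condition"),
                   list(message = sprintf(
                     "glomerulus '%s' excluded: %d valid areas < minimum %d",
                     gid, nrow(valid), min_areas),
                     call = NULL, glomerulus_id = gid,
                     n_valid = nrow(valid))))
  }
  data.frame(sample_id = valid$sample_id[1],
             glomerulus_id = gid,
             n_areas = nrow(valid),
             mean_ratio = mean(valid$ratio),
             mean_fsd_per_um = mean(valid$fsd_per_um),
             stringsAsFactors = FALSE)
}

#' Summarize all glomeruli in a measurement table
#'
#' Applies [summarize_glomerulus()] per glomerulus, collecting exclusions
#' (too few valid areas) instead of failing.
#'
#' @param records data.frame of [measure_area()] rows.
#' @param min_areas minimum number of valid areas per glomerulus.
#' @return list with `summaries` (data.frame) and `excluded` (data.frame of
#'   `glomerulus_id`, `n_valid`, `reason`).
#' @export
summarize_glomeruli <- function(records, min_areas = 20L) {
  summaries <- list()
  excluded <- list()
  for (gid in unique(records$glomerulus_id)) {
    sub <- records[records$glomerulus_id == gid, , drop = FALSE]
    res <- tryCatch(summarize_glomerulus(sub, min_areas = min_areas),
                    slitmorph_exclusion = function(e) e)
    if (inherits(res, "slitmorph_exclusion")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(glomerulus_id = gid, n_valid = res$n_valid,
                   reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      summaries[[length(summaries) + 1L]] <- res
    }
  }
  list(
    summaries = if (length(summaries)) do.call(rbind, summaries) else
      data.frame(sample_id = character(0), glomerulus_id = character(0),
                 n_areas = integer(0), mean_ratio = numeric(0),
                 mean_fsd_per_um = numeric(0)),
    excluded = if (length(excluded)) do.call(rbind, excluded) else
      data.frame(glomerulus_id = character(0), n_valid = integer(0),
                 reason = character(0))
  )
}
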