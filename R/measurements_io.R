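# CSV output for per-ROI measurements and per-glomerulus summaries.

measurement_columns <- c(
  "sample_id", "glomerulus_id", "roi_id",
  "nephrin_area_um2", "cldn5_area_um2", "ratio",
  "l_fs_um", "roi_area_um2", "fsd_per_um", "phase",
  "continuity_gaps_per_um", "nephrin_threshold", "cldn5_threshold", "valid"
)

summary_columns <- c("sample_id", "glomerulus_id", "n_areas",
                     "mean_ratio", "mean_fsd_per_um")

row_kind <- function(df) {
  if (all(measurement_columns %in% names(df))) return("measurement")
  if (all(summary_columns %in% names(df))) return("summary")
  NA_character_
}

#' Write measurement or summary rows to CSV
#'
#' One row per record, header included, stable column order (per-ROI
#' measurement columns: sample_id, glomerulus_id, roi_id, nephrin_area_um2,
#' cldn5_area_um2, ratio, l_fs_um, roi_area_um2, fsd_per_um, phase, plus
#' provenance columns). Measurement and summary rows cannot be mixed in one
#' file.
#'
#' @param rows data.frame of [measure_area()] records or
#'   [summarize_glomerulus()] summaries (or a list of such one-row frames of
#'   a single kind).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(rows, path) {
  if (is.list(rows) && !is.data.frame(rows)) {
    kinds <- unique(vapply(rows, function(r) row_kind(as.data.frame(r)),
                           character(1)))
    if (length(kinds) > 1L || anyNA(kinds)) {
      stop("mixed or unknown row types; write one record type per file",
           call. = FALSE)
    }
    rows <- do.call(rbind, lapply(rows, as.data.frame))
  }
  if (!is.data.frame(rows)) stop("`rows` must be a data.frame", call. = FALSE)
  kind <- row_kind(rows)
  if (is.na(kind) && nrow(rows) == 0L && ncol(rows) == 0L) {
    kind <- "measurement"
    rows <- empty_measurements()
  }
  if (is.na(kind)) stop("unknown row type", call. = FALSE)
  cols <- if (kind == "measurement") measurement_columns else summary_columns
  utils::write.csv(rows[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a measurements/summary CSV written by [write_measurements()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_measurements <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

empty_measurements <- function() {
  df <- as.data.frame(stats::setNames(
    rep(list(numeric(0)), length(measurement_columns)), measurement_columns))
  for (ch in c("sample_id", "glomerulus_id", "roi_id", "phase")) {
    df[[ch]] <- character(0)
  }
  df$valid <- logical(0)
  df
}
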