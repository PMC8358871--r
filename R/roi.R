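# Polygon regions of interest delineating evaluable filtration-slit areas.

#' Region of interest over a filtration-slit area
#'
#' A simple (non-self-intersecting) polygon in pixel coordinates with an
#' attached physical pixel size. The pixel convention is 0-based with pixel
#' centers at integer coordinates; a pixel belongs to the ROI iff its center
#' lies inside the polygon (boundary counts as inside).
#'
#' @param vertices n x 2 numeric matrix (columns x, y) of polygon vertices in
#'   pixel coordinates, n >= 3.
#' @param roi_id unique ROI identifier.
#' @param glomerulus_id identifier of the glomerulus the area belongs to.
#' @param pixel_size_um pixel size in micrometres.
#' @return an object of class `slit_roi`.
#' @examples
#' r <- slit_roi(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), "r1", "g1", 0.17)
#' roi_area_um2(r)
#' @export
slit_roi <- function(vertices, roi_id, glomerulus_id = "g1",
                     pixel_size_um = 1) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L || nrow(vertices) < 3L) {
    stop("`vertices` must be a numeric n x 2 matrix with n >= 3", call. = FALSE)
  }
  if (any(!is.finite(vertices))) stop("vertices must be finite", call. = FALSE)
  if (polygon_self_intersects(vertices)) {
    stop(sprintf("ROI '%s' rejected: polygon is self-intersecting", roi_id),
         call. = FALSE)
  }
  if (polygon_area(vertices) <= 0) {
    stop(sprintf("ROI '%s' rejected: zero enclosed area", roi_id),
         call. = FALSE)
  }
  stop_if_not_scalar_number(pixel_size_um, "pixel_size_um", min = 1e-9)
  structure(list(roi_id = as.character(roi_id),
                 glomerulus_id = as.character(glomerulus_id),
                 vertices = unname(vertices),
                 pixel_size_um = pixel_size_um),
            class = "slit_roi")
}

#' @export
print.slit_roi <- function(x, ...) {
  cat(sprintf("slit_roi '%s' (glomerulus '%s'): %d vertices, area %.2f um2\n",
              x$roi_id, x$glomerulus_id, nrow(x$vertices), roi_area_um2(x)))
  invisible(x)
}

#' Physical area enclosed by an ROI polygon
#'
#' Shoelace polygon area converted to square micrometres; this is the
#' denominator A of the filtration slit density.
#'
#' @param roi a [slit_roi()].
#' @return area in um^2.
#' @export
roi_area_um2 <- function(roi) {
  polygon_area(roi$vertices) * roi$pixel_size_um^2
}

#' Rasterize an ROI to a pixel-membership mask
#'
#' A pixel (0-based indices) is in the ROI iff its center lies inside the
#' polygon, boundary included (even-odd rule).
#'
#' @param roi a [slit_roi()].
#' @param dim image dimensions c(ny, nx).
#' @return logical ny x nx matrix.
#' @export
roi_mask <- function(roi, dim) {
  ny <- dim[1]
  nx <- dim[2]
  v <- roi$vertices
  # restrict point-in-polygon tests to the polygon bounding box
  cx0 <- max(0L, floor(min(v[, 1])))
  cx1 <- min(nx - 1L, ceiling(max(v[, 1])))
  cy0 <- max(0L, floor(min(v[, 2])))
  cy1 <- min(ny - 1L, ceiling(max(v[, 2])))
  out <- matrix(FALSE, ny, nx)
  if (cx1 < cx0 || cy1 < cy0) return(out)
  xs <- seq.int(cx0, cx1)
  ys <- seq.int(cy0, cy1)
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  inside <- pracma::inpolygon(gx, gy, v[, 1], v[, 2], boundary = TRUE)
  out[cbind(gy + 1L, gx + 1L)] <- inside
  out
}

#' Read ROIs from a JSON polygon file
#'
#' The schema is an object with a `rois` array; each entry has `roi_id`,
#' `glomerulus_id`, `pixel_size_um`, and `vertices` (array of \[x, y\] pixel
#' coordinates). Self-intersecting polygons, fewer than three vertices, and
#' duplicate `roi_id`s are rejected.
#'
#' @param path JSON file path.
#' @return list of [slit_roi()] objects.
#' @seealso [write_rois()]
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- doc$rois %||% doc
  if (length(entries) == 0L) stop("no ROIs in file", call. = FALSE)
  rois <- lapply(entries, function(en) {
    verts <- do.call(rbind, lapply(en$vertices, function(vv) {
      as.numeric(unlist(vv))
    }))
    slit_roi(verts, roi_id = en$roi_id,
             glomerulus_id = en$glomerulus_id %||% "g1",
             pixel_size_um = en$pixel_size_um %||% 1)
  })
  ids <- vapply(rois, function(r) r$roi_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate roi_id: ", paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "), call. = FALSE)
  }
  rois
}

#' Write ROIs to a JSON polygon file
#'
#' @param rois list of [slit_roi()] objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  if (inherits(rois, "slit_roi")) rois <- list(rois)
  entries <- lapply(rois, function(r) {
    list(roi_id = r$roi_id,
         glomerulus_id = r$glomerulus_id,
         pixel_size_um = r$pixel_size_um,
         vertices = lapply(seq_len(nrow(r$vertices)),
                           function(i) as.numeric(r$vertices[i, ])))
  })
  jsonlite::write_json(list(format = "slitmorph-rois", rois = entries), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
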