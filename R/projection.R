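# Z-projection and per-channel binarization.

#' Maximum intensity projection of one channel
#'
#' Each output pixel is the maximum over the selected z range of the chosen
#' channel. A z window can be used to keep signal from other focal planes
#' (for claudin-5: capillary endothelium) out of the projection.
#'
#' @param stack a [channel_stack()].
#' @param channel channel name.
#' @param z_min,z_max optional 1-based inclusive slice window; defaults to
#'   the full stack.
#' @return numeric matrix with attribute `pixel_size_um`.
#' @export
max_intensity_projection <- function(stack, channel, z_min = NULL,
                                     z_max = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!channel %in% names(stack$channels)) {
    stop("unknown channel: ", channel, call. = FALSE)
  }
  a <- stack$channels[[channel]]
  nz <- dim(a)[3]
  z0 <- as.integer(z_min %||% 1L)
  z1 <- as.integer(z_max %||% nz)
  if (z0 < 1L || z1 > nz || z0 > z1) {
    stop(sprintf("invalid z window [%d, %d] for %d slices", z0, z1, nz),
         call. = FALSE)
  }
  sub <- a[, , z0:z1, drop = FALSE]
  img <- apply(sub, c(1, 2), max)
  attr(img, "pixel_size_um") <- stack$pixel_size_um
  img
}

#' Otsu threshold of an intensity sample
#'
#' Exhaustive sweep over 256 histogram bin edges maximizing the
#' between-class variance. Constant input has no separable classes and is
#' an error.
#'
#' @param values numeric vector of intensities (e.g. the ROI-restricted
#'   pixels of a projection).
#' @param n_bins number of histogram bins.
#' @return threshold intensity; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite intensities", call. = FALSE)
  lo <- min(values)
  hi <- max(values)
  if (hi - lo <= .Machine$double.eps * max(1, abs(hi))) {
    stop("constant image: Otsu threshold undefined (no separable classes)",
         call. = FALSE)
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(values, edges,
                                            rightmost.closed = TRUE), 1L),
                          n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w <- cumsum(counts)
  mu <- cumsum(counts * mids)
  n <- w[n_bins]
  mu_t <- mu[n_bins]
  # between-class variance for a cut after bin k
  k <- seq_len(n_bins - 1L)
  w0 <- w[k]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mu_t * w0[valid] / n - mu[k][valid])^2 * n /
    (w0[valid] * w1[valid] / n) / n
  best <- which.max(bcv)
  edges[best + 1L]
}

#' Binarize a projected image
#'
#' A pixel is foreground iff its intensity is strictly greater than the
#' threshold. With `method = "otsu"` the threshold is computed on the
#' ROI-restricted histogram when an ROI is supplied, else on the full image;
#' `method = "fixed"` uses `fixed_threshold` as-is.
#'
#' @param image numeric matrix (e.g. from [max_intensity_projection()]).
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold threshold intensity, required for
#'   `method = "fixed"`.
#' @param roi optional [slit_roi()] restricting the Otsu histogram.
#' @param pixel_size_um pixel size; defaults to the image's
#'   `pixel_size_um` attribute.
#' @param channel_name label recorded on the mask.
#' @return object of class `binary_mask`: list with logical `grid`,
#'   `pixel_size_um`, `channel_name`, `threshold_used`, `method`.
#' @export
binarize <- function(image, method = c("otsu", "fixed"),
                     fixed_threshold = NULL, roi = NULL,
                     pixel_size_um = NULL, channel_name = "") {
  method <- match.arg(method)
  px <- pixel_size_um %||% attr(image, "pixel_size_um")
  if (is.null(px)) {
    stop("pixel size unknown; pass `pixel_size_um`", call. = FALSE)
  }
  if (method == "fixed") {
    if (is.null(fixed_threshold)) {
      stop("`fixed_threshold` required for method = 'fixed'", call. = FALSE)
    }
    thr <- fixed_threshold
  } else {
    vals <- if (is.null(roi)) {
      as.numeric(image)
    } else {
      as.numeric(image[roi_mask(roi, dim(image))])
    }
    thr <- otsu_threshold(vals)
  }
  structure(list(grid = unname(image > thr),
                 pixel_size_um = px,
                 channel_name = channel_name,
                 threshold_used = thr,
                 method = method),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask '%s': %d x %d px, %d positive, threshold %.4g (%s)\n",
              x$channel_name, nrow(x$grid), ncol(x$grid), sum(x$grid),
              x$threshold_used, x$method))
  invisible(x)
}

#' Positive area of a mask within an ROI
#'
#' Counts foreground pixels whose centers lie inside the ROI polygon and
#' converts to physical area.
#'
#' @param mask a `binary_mask` from [binarize()].
#' @param roi a [slit_roi()]; must share the mask's pixel size.
#' @return area in um^2.
#' @export
positive_area <- function(mask, roi) {
  stopifnot(inherits(mask, "binary_mask"), inherits(roi, "slit_roi"))
  if (abs(mask$pixel_size_um - roi$pixel_size_um) >
      1e-9 * max(mask$pixel_size_um, roi$pixel_size_um)) {
    stop("pixel-size mismatch between mask and ROI", call. = FALSE)
  }
  sum(mask$grid & roi_mask(roi, dim(mask$grid))) * mask$pixel_size_um^2
}
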