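# Multi-channel z-stack container and TIFF input/output.

#' Two-channel 3D image stack
#'
#' Container for per-channel voxel grids with physical pixel and z spacing.
#' Channels are stored as `(y, x, z)` arrays sharing dimensions.
#'
#' @param channels named list of 3D numeric arrays (or matrices, treated as
#'   single-slice stacks); typical names are `nephrin` and `cldn5`.
#' @param pixel_size_um lateral pixel size in micrometres.
#' @param z_step_um slice-to-slice distance in micrometres.
#' @return an object of class `channel_stack`.
#' @examples
#' s <- channel_stack(list(nephrin = array(0, c(4, 4, 2)),
#'                         cldn5 = array(0, c(4, 4, 2))),
#'                    pixel_size_um = 0.17, z_step_um = 0.2)
#' dim(s$channels$nephrin)
#' @export
channel_stack <- function(channels, pixel_size_um, z_step_um = 0.2) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(names(channels) == "")) {
    stop("`channels` must be a non-empty named list of arrays", call. = FALSE)
  }
  channels <- lapply(channels, function(a) {
    if (is.matrix(a)) dim(a) <- c(dim(a), 1L)
    if (length(dim(a)) != 3L) {
      stop("each channel must be a (y, x, z) array", call. = FALSE)
    }
    if (!all(is.finite(a))) stop("intensities must be finite", call. = FALSE)
    if (any(a < 0)) stop("intensities must be non-negative", call. = FALSE)
    a
  })
  d <- dim(channels[[1]])
  for (a in channels) {
    if (!identical(dim(a), d)) {
      stop("all channels must share dimensions", call. = FALSE)
    }
  }
  stop_if_not_scalar_number(pixel_size_um, "pixel_size_um", min = 1e-9)
  stop_if_not_scalar_number(z_step_um, "z_step_um", min = 1e-9)
  structure(list(channels = channels,
                 pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("channel_stack: %s; %d x %d px, %d z @ %.4f um/px, dz = %.2f um\n",
              paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3], x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' Number of z slices of a stack
#' @param stack a [channel_stack()].
#' @return integer slice count.
#' @export
n_slices <- function(stack) dim(stack$channels[[1]])[3]

stack_meta_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.json")
}

#' Write a channel stack as multi-page TIFF
#'
#' Pages are channel-interleaved in z-major order (z1/ch1, z1/ch2, z2/ch1,
#' ...), stored as 32-bit float. Because baseline TIFF float storage is
#' restricted to \[0, 1\], voxels are divided by a recorded intensity scale;
#' physical pixel size, z step, channel names, and that scale are written to
#' a JSON metadata sidecar (`<stem>.meta.json`) next to the image.
#'
#' @param stack a [channel_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @seealso [read_stack()]
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  nz <- n_slices(stack)
  chn <- names(stack$channels)
  scale <- max(1e-12, max(vapply(stack$channels, max, numeric(1))))
  pages <- vector("list", nz * length(chn))
  i <- 0L
  for (k in seq_len(nz)) {
    for (ch in chn) {
      i <- i + 1L
      pages[[i]] <- stack$channels[[ch]][, , k] / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(format = "slitmorph-stack", version = 1L,
               channel_names = chn,
               pixel_size_um = stack$pixel_size_um,
               z_step_um = stack$z_step_um,
               n_z = nz,
               intensity_scale = scale)
  jsonlite::write_json(meta, stack_meta_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a multi-page TIFF as a channel stack
#'
#' Reads a channel-interleaved multi-page TIFF written by [write_stack()]
#' (or any TIFF whose page count is divisible by the channel count).
#' Pixel size and channel names come from the JSON metadata sidecar when
#' present, and can be overridden by arguments; without either source of
#' pixel size this is an error.
#'
#' @param path TIFF path.
#' @param channels optional character vector of channel names; overrides the
#'   sidecar. Required when no sidecar exists.
#' @param pixel_size_um optional pixel size override, micrometres.
#' @param z_step_um optional z step override, micrometres.
#' @return a [channel_stack()].
#' @export
read_stack <- function(path, channels = NULL, pixel_size_um = NULL,
                       z_step_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- NULL
  mp <- stack_meta_path(path)
  if (file.exists(mp)) meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  chn <- channels %||% meta$channel_names
  if (is.null(chn)) {
    stop("channel names unknown: no metadata sidecar and no `channels` given",
         call. = FALSE)
  }
  px <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(px)) {
    stop("pixel size unknown: no metadata sidecar and no `pixel_size_um` override",
         call. = FALSE)
  }
  dz <- z_step_um %||% meta$z_step_um %||% 0.2
  scale <- meta$intensity_scale %||% 1

  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nch <- length(chn)
  if (length(pages) %% nch != 0L) {
    stop(sprintf("format error: %d pages not divisible by %d channels",
                 length(pages), nch), call. = FALSE)
  }
  d <- dim(pages[[1]])
  if (!all(vapply(pages, function(pg) identical(dim(pg), d), logical(1)))) {
    stop("format error: ragged page dimensions", call. = FALSE)
  }
  nz <- length(pages) %/% nch
  arrs <- lapply(seq_len(nch), function(c_i) {
    a <- array(0, dim = c(d[1], d[2], nz))
    for (k in seq_len(nz)) {
      pg <- pages[[(k - 1L) * nch + c_i]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # greyscale stored with alpha
      a[, , k] <- pg * scale
    }
    a
  })
  names(arrs) <- chn
  channel_stack(arrs, pixel_size_um = px, z_step_um = dz)
}
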