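# Synthetic two-channel filtration-slit field generator.
#
# The model: smooth, roughly vertical slit curves (one per filtration slit)
# cross a rectangular evaluable region. Interdigitation is a damped meander:
# amplitude a = A0 * (1 - e), spacing s = S0 * (1 + e). Claudin-5 decorates an
# exact arc fraction c(e) of each curve in randomly placed segments; nephrin
# is erased over an exact arc fraction g(e) once e > 0.5. Curves are stamped
# as line integrals on a supersampled grid, blurred with a Gaussian PSF,
# box-downsampled, replicated over z under a focal envelope and corrupted
# with Poisson + Gaussian noise. Ground truth is kept at vector level.

# ---- polyline helpers -------------------------------------------------------

# Arc length of an n x 2 polyline.
polyline_length <- function(v) {
  if (nrow(v) < 2L) return(0)
  sum(sqrt(diff(v[, 1])^2 + diff(v[, 2])^2))
}

# Cumulative arc length at each vertex.
polyline_cumlen <- function(v) {
  c(0, cumsum(sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)))
}

# Extract the sub-polyline between arc positions a < b (linear interpolation
# at the cut points, so slice lengths are exact).
slice_polyline <- function(v, cum, a, b) {
  total <- cum[length(cum)]
  a <- max(0, min(a, total))
  b <- max(0, min(b, total))
  if (b <= a) return(NULL)
  inner <- which(cum > a & cum < b)
  xs <- stats::approx(cum, v[, 1], xout = c(a, b), ties = "ordered")$y
  ys <- stats::approx(cum, v[, 2], xout = c(a, b), ties = "ordered")$y
  out <- rbind(c(xs[1], ys[1]),
               v[inner, , drop = FALSE],
               c(xs[2], ys[2]))
  out
}

# Randomly place `n_pieces` disjoint intervals with total length
# `fraction * L` along [0, L]; gaps between pieces are exponential
# stick-breaking. Returns a 2-column matrix (start, end), possibly empty.
arc_intervals <- function(L, fraction, mean_piece_um) {
  if (fraction <= 0 || L <= 0) return(matrix(numeric(0), ncol = 2))
  if (fraction >= 1) return(matrix(c(0, L), ncol = 2))
  n <- max(1L, round(L * fraction / mean_piece_um))
  piece <- L * fraction / n
  free <- L - n * piece
  w <- stats::rexp(n + 1L)
  gaps <- free * w / sum(w)
  starts <- cumsum(gaps)[seq_len(n)] + piece * (seq_len(n) - 1L)
  unname(cbind(starts, starts + piece))
}

# Complement of a sorted interval set within [0, L].
complement_intervals <- function(iv, L) {
  if (nrow(iv) == 0L) return(matrix(c(0, L), ncol = 2))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  starts <- c(0, iv[, 2])
  ends <- c(iv[, 1], L)
  keep <- ends - starts > 1e-12
  cbind(starts[keep], ends[keep])
}

# ---- rasterization ----------------------------------------------------------

# Stamp polylines as line integrals onto a (ny x nx) grid with pixel size
# `px_um`: each segment midpoint deposits its segment length (in um) into
# the pixel containing it. Pixel (i, j) covers
# [(j-1) px, j px) x [(i-1) px, i px) in um coordinates.
stamp_polylines <- function(polys, ny, nx, px_um) {
  acc <- numeric(ny * nx)
  for (v in polys) {
    if (is.null(v) || nrow(v) < 2L) next
    mx <- (v[-nrow(v), 1] + v[-1, 1]) / 2
    my <- (v[-nrow(v), 2] + v[-1, 2]) / 2
    w <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
    ix <- pmin(pmax(floor(mx / px_um), 0), nx - 1L)
    iy <- pmin(pmax(floor(my / px_um), 0), ny - 1L)
    idx <- iy + ix * ny + 1
    s <- rowsum(w, idx)
    at <- as.numeric(rownames(s))
    acc[at] <- acc[at] + s[, 1]
  }
  matrix(acc, ny, nx)
}

# Gaussian blur via EBImage; returns a plain matrix.
blur2d <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  out <- EBImage::gblur(m, sigma = sigma_px)
  as.matrix(EBImage::imageData(out))
}

# Box-downsample a (ny*ss x nx*ss) matrix by factor ss (mean pooling).
box_downsample <- function(m, ss) {
  if (ss == 1L) return(m)
  ny <- nrow(m) %/% ss
  nx <- ncol(m) %/% ss
  dim(m) <- c(ss, ny, ss * nx)
  t1 <- colSums(m) / ss                 # (ny, ss*nx)
  dim(t1) <- c(ny, ss, nx)
  t2 <- aperm(t1, c(2, 1, 3))
  out <- colSums(matrix(t2, ss, ny * nx)) / ss
  matrix(out, ny, nx)
}

# ---- generator --------------------------------------------------------------

#' Generate a synthetic two-channel filtration-slit field
#'
#' Produces a nephrin / claudin-5 z-stack with known vector-level ground
#' truth across the effacement continuum. See [synth_params()] for the
#' geometric and noise model. Identical parameters (including seed) give
#' bit-identical output.
#'
#' @param params a [synth_params()] object.
#' @return a list with elements `stack` (a [channel_stack()] with channels
#'   `nephrin` and `cldn5`), `truth` (class `ground_truth`: `slit_polylines`
#'   in um coordinates after nephrin gap erasure, `total_slit_length_um`,
#'   `roi_polygon_px`, `roi_area_um2`, `cldn5_covered_length_um`,
#'   `true_fsd_per_um`, `true_coverage`), and `roi` (the evaluable region as
#'   a [slit_roi()]).
#' @examples
#' f <- generate_slit_field(synth_params(field_size_px = c(64, 64),
#'                                       roi_margin_um = 1, seed = 3))
#' f$truth$true_fsd_per_um
#' @export
generate_slit_field <- function(params) {
  if (!inherits(params, "synth_params")) {
    stop("`params` must be created by synth_params()", call. = FALSE)
  }
  p <- params
  px <- p$pixel_size_um
  ny <- p$field_size_px[1]
  nx <- p$field_size_px[2]
  W <- nx * px
  H <- ny * px
  e <- p$effacement

  s_eff <- p$slit_spacing_um * (1 + e)
  a_eff <- p$meander_amplitude_um * (1 - e)
  if (s_eff < 2 * px) {
    stop(sprintf(
      "degenerate geometry: effective slit spacing %.3f um is below two pixels (%.3f um)",
      s_eff, 2 * px), call. = FALSE)
  }
  m <- p$roi_margin_um
  if (W - 2 * m < 3 * s_eff || H - 2 * m < 2) {
    stop("field too small for the requested margin and slit spacing",
         call. = FALSE)
  }

  with_local_seed(p$seed, {
    # --- slit curve geometry (um coordinates) ---
    x0 <- m
    x1 <- W - m
    y0 <- m
    y1 <- H - m
    usable0 <- x0 + a_eff + 0.05
    usable1 <- x1 - a_eff - 0.05
    n_curves <- floor((usable1 - usable0) / s_eff) + 1L
    offset <- (usable1 - usable0 - (n_curves - 1L) * s_eff) / 2
    base_x <- usable0 + offset + (seq_len(n_curves) - 1L) * s_eff +
      stats::runif(n_curves, -0.02 * s_eff, 0.02 * s_eff)
    phase0 <- stats::runif(1, 0, 2 * pi)
    phases <- phase0 + stats::rnorm(n_curves, sd = 0.05)
    amps <- a_eff * stats::runif(n_curves, 0.95, 1.05)

    yy <- seq(y0, y1, by = 0.02)
    if (yy[length(yy)] < y1) yy <- c(yy, y1)  # curves span the full ROI height
    coverage <- cldn5_coverage_at(p)
    gap_frac <- nephrin_gap_at(p)

    nephrin_polys <- list()
    cldn5_polys <- list()
    total_len <- 0
    retained_len <- 0
    covered_len <- 0
    for (k in seq_len(n_curves)) {
      v <- cbind(base_x[k] + amps[k] * sin(2 * pi * yy / p$meander_wavelength_um
                                           + phases[k]),
                 yy)
      cum <- polyline_cumlen(v)
      L <- cum[length(cum)]
      total_len <- total_len + L

      gaps <- arc_intervals(L, gap_frac, p$nephrin_gap_segment_um)
      keep <- complement_intervals(gaps, L)
      for (r in seq_len(nrow(keep))) {
        sub <- slice_polyline(v, cum, keep[r, 1], keep[r, 2])
        if (!is.null(sub)) {
          nephrin_polys[[length(nephrin_polys) + 1L]] <- sub
          retained_len <- retained_len + (keep[r, 2] - keep[r, 1])
        }
      }

      dec <- arc_intervals(L, coverage, p$cldn5_segment_um)
      for (r in seq_len(nrow(dec))) {
        sub <- slice_polyline(v, cum, dec[r, 1], dec[r, 2])
        if (!is.null(sub)) {
          cldn5_polys[[length(cldn5_polys) + 1L]] <- sub
          covered_len <- covered_len + (dec[r, 2] - dec[r, 1])
        }
      }
    }

    # --- rendering ---
    ss <- p$supersample
    px_ss <- px / ss
    sigma_um <- p$psf_fwhm_um / (2 * sqrt(2 * log(2)))
    sigma_px_ss <- sigma_um / px_ss
    norm <- sqrt(2 * pi) * sigma_um / px_ss^2  # line peak ~ 1 after blur

    render_channel <- function(polys) {
      d <- stamp_polylines(polys, ny * ss, nx * ss, px_ss)
      img <- blur2d(d * norm, sigma_px_ss)
      box_downsample(img, ss)
    }
    nephrin_img <- render_channel(nephrin_polys)
    cldn5_img <- render_channel(cldn5_polys)

    # --- endothelial / arteriolar clutter outside the ROI ---
    if (p$endothelial_clutter && m >= 1.5) {
      xc <- (seq_len(nx) - 0.5) * px
      yc <- (seq_len(ny) - 0.5) * px
      n_blobs <- 3L
      for (b in seq_len(n_blobs)) {
        side <- sample.int(4L, 1L)
        depth <- stats::runif(1, 0.2, 0.7)   # distance from field border, um
        along <- stats::runif(1, 0.1, 0.9)
        cx <- switch(side, depth, W - depth, along * W, along * W)
        cy <- switch(side, along * H, along * H, depth, H - depth)
        amp <- stats::runif(1, 0.5, 1)
        sd_b <- stats::runif(1, 0.35, 0.6)
        blob <- amp * outer(exp(-(yc - cy)^2 / (2 * sd_b^2)),
                            exp(-(xc - cx)^2 / (2 * sd_b^2)))
        cldn5_img <- cldn5_img + blob
      }
    }

    # --- z replication, focal envelope, noise ---
    z_pos <- (seq_len(p$n_z) - 1L) * p$z_step_um
    z_mid <- (p$n_z - 1L) * p$z_step_um / 2
    env <- exp(-(z_pos - z_mid)^2 / (2 * p$axial_sd_um^2))

    make_stack_channel <- function(img) {
      arr <- array(0, dim = c(ny, nx, p$n_z))
      for (k in seq_len(p$n_z)) {
        plane <- pmax(img, 0) * env[k]  # FFT blur can leave tiny negatives
        if (is.finite(p$photon_scale)) {
          plane <- stats::rpois(length(plane), p$photon_scale * plane) /
            p$photon_scale
          dim(plane) <- c(ny, nx)
        }
        if (p$read_noise_sd > 0) {
          plane <- plane + matrix(stats::rnorm(ny * nx, sd = p$read_noise_sd),
                                  ny, nx)
        }
        arr[, , k] <- pmax(plane, 0)
      }
      arr
    }
    stack <- channel_stack(
      channels = list(nephrin = make_stack_channel(nephrin_img),
                      cldn5 = make_stack_channel(cldn5_img)),
      pixel_size_um = px,
      z_step_um = p$z_step_um
    )

    # --- ROI (pixel coordinates; pixel centers sit at integer coords) ---
    to_px <- function(u) u / px - 0.5
    roi_vertices <- cbind(to_px(c(x0, x1, x1, x0)), to_px(c(y0, y0, y1, y1)))
    roi <- slit_roi(roi_vertices, roi_id = "roi_full", glomerulus_id = "synthetic",
                    pixel_size_um = px)
    roi_area <- (x1 - x0) * (y1 - y0)

    truth <- structure(list(
      slit_polylines = nephrin_polys,
      total_slit_length_um = unname(retained_len),
      base_slit_length_um = unname(total_len),
      roi_polygon_px = roi_vertices,
      roi_area_um2 = unname(roi_area),
      cldn5_covered_length_um = unname(covered_len),
      true_fsd_per_um = unname(retained_len / roi_area),
      true_coverage = unname(
        if (retained_len > 0) covered_len / retained_len else NA_real_),
      n_curves = n_curves,
      params = p
    ), class = "ground_truth")

    list(stack = stack, truth = truth, roi = roi)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "ground_truth: %d slit segments, l_FS = %.1f um, A = %.1f um2, FSD = %.3f /um, coverage = %.3f\n",
    length(x$slit_polylines), x$total_slit_length_um, x$roi_area_um2,
    x$true_fsd_per_um, x$true_coverage))
  invisible(x)
}

#' Analytic filtration slit density from generator ground truth
#'
#' FSD at truth level: total (post-gap) nephrin-positive slit arc length
#' divided by the evaluable area, in 1/um.
#'
#' @param truth a `ground_truth` object from [generate_slit_field()], or a
#'   list with fields `total_slit_length_um` and `roi_area_um2`.
#' @return FSD in 1/um.
#' @examples
#' analytic_fsd(list(total_slit_length_um = 50, roi_area_um2 = 25))
#' @export
analytic_fsd <- function(truth) {
  if (is.null(truth$roi_area_um2) || !is.finite(truth$roi_area_um2) ||
      truth$roi_area_um2 <= 0) {
    stop("ROI area must be positive", call. = FALSE)
  }
  truth$total_slit_length_um / truth$roi_area_um2
}

#' Default synthetic cohort design
#'
#' Three groups mirroring the study design: 4 controls with mild effacement,
#' 5 MCD-like and 5 FSGS-like samples with substantial effacement.
#'
#' @return list of group specs usable by [generate_cohort()], each with
#'   `label`, `n`, and a uniform effacement range `e_range`.
#' @export
default_cohort_spec <- function() {
  list(
    list(label = "control", n = 4L, e_range = c(0, 0.15)),
    list(label = "MCD", n = 5L, e_range = c(0.5, 0.8)),
    list(label = "FSGS", n = 5L, e_range = c(0.5, 0.9))
  )
}

#' Generate a synthetic cohort of slit fields
#'
#' One stack + ground truth per sample. Per-sample seeds and effacement
#' levels are derived deterministically from the master seed, so the same
#' seed always yields the same cohort.
#'
#' @param group_specs list of group specifications; each element is a list
#'   with `label` (string), `n` (samples, >= 1), and either `e_range`
#'   (length-2 numeric, uniform effacement distribution on \[0, 1\]) or
#'   `e_fun` (function(n) returning n effacement values in \[0, 1\]).
#' @param seed master integer seed.
#' @param params a [synth_params()] template; `effacement` and `seed` are
#'   overridden per sample.
#' @return list of samples, each a list with `stack`, `truth`, `roi`,
#'   `label`, `sample_id`, `effacement`.
#' @examples
#' specs <- list(list(label = "control", n = 1L, e_range = c(0, 0.1)))
#' cohort <- generate_cohort(specs, seed = 1,
#'                           params = synth_params(field_size_px = c(64, 64),
#'                                                 roi_margin_um = 1))
#' length(cohort)
#' @export
generate_cohort <- function(group_specs, seed,
                            params = synth_params()) {
  if (!is.list(group_specs) || length(group_specs) == 0L) {
    stop("`group_specs` must be a non-empty list of group specifications",
         call. = FALSE)
  }
  for (g in group_specs) {
    if (is.null(g$label) || is.null(g$n) || g$n < 1) {
      stop("each group spec needs a `label` and `n` >= 1", call. = FALSE)
    }
  }
  plan <- with_local_seed(seed, {
    rows <- list()
    for (g in group_specs) {
      n <- as.integer(g$n)
      e <- if (!is.null(g$e_fun)) {
        g$e_fun(n)
      } else {
        r <- g$e_range %||% c(0, 1)
        stats::runif(n, r[1], r[2])
      }
      if (any(e < 0 | e > 1)) {
        stop("effacement distribution must be supported on [0, 1]",
             call. = FALSE)
      }
      seeds <- sample.int(.Machine$integer.max - 1L, n)
      for (i in seq_len(n)) {
        rows[[length(rows) + 1L]] <- list(label = g$label, e = e[i],
                                          seed = seeds[i])
      }
    }
    rows
  })
  lapply(seq_along(plan), function(i) {
    row <- plan[[i]]
    p <- params
    p$effacement <- row$e
    p$seed <- row$seed
    field <- generate_slit_field(p)
    sample_id <- sprintf("%s_%02d", row$label, i)
    field$roi$glomerulus_id <- sample_id
    list(stack = field$stack, truth = field$truth, roi = field$roi,
         label = row$label, sample_id = sample_id, effacement = row$e)
  })
}
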