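#' Parameters for the synthetic slit-field generator
#'
#' Bundles and validates every knob of the two-channel filtration-slit
#' simulator. The single control that matters biologically is `effacement`
#' (e in \[0, 1\]): at e = 0 slit curves meander at full amplitude with tight
#' spacing (interdigitating foot processes); as e grows the meander flattens
#' (amplitude scales with 1 - e), slits spread apart (spacing scales with
#' 1 + e), claudin-5 decoration of the slit grows from the basal focal
#' coverage `cldn5_basal_coverage` towards continuous lines following
#' c(e) = c0 + (1 - c0) * e^gamma, and beyond e = 0.5 nephrin develops gaps
#' covering an arc fraction g1 * max(0, 2e - 1).
#'
#' @param field_size_px integer pair, image size in pixels (rows, cols).
#' @param pixel_size_um lateral pixel size in micrometres (default
#'   1/5.853, the human acquisition scale).
#' @param n_z number of z slices.
#' @param z_step_um slice-to-slice distance in micrometres (default 0.2).
#' @param effacement effacement level e in \[0, 1\].
#' @param slit_spacing_um mean distance between adjacent slit curves at
#'   e = 0, micrometres.
#' @param meander_amplitude_um interdigitation meander amplitude at e = 0,
#'   micrometres.
#' @param meander_wavelength_um meander wavelength, micrometres.
#' @param cldn5_basal_coverage c0 in \[0, 1\]: fraction of slit arc length
#'   decorated by claudin-5 at e = 0 (focal co-localization).
#' @param cldn5_coupling_exponent gamma > 0 in the coverage law
#'   c(e) = c0 + (1 - c0) * e^gamma; gamma < 1 makes claudin-5 recruitment
#'   lead effacement.
#' @param cldn5_segment_um mean arc length of one decorated segment.
#' @param nephrin_gap_fraction_max g1 in \[0, 1): arc fraction of nephrin
#'   erased at e = 1.
#' @param nephrin_gap_segment_um mean arc length of one nephrin gap.
#' @param psf_fwhm_um lateral PSF full width at half maximum (default
#'   0.115, the effective super-resolution scale).
#' @param photon_scale photons per unit normalized intensity for the
#'   Poisson noise component; `Inf` disables photon noise.
#' @param read_noise_sd additive Gaussian noise standard deviation on the
#'   normalized intensity scale; 0 disables it.
#' @param endothelial_clutter logical; add off-ROI claudin-5 blobs
#'   mimicking endothelial/arteriolar signal outside the evaluable area.
#' @param roi_margin_um margin between the field border and the evaluable
#'   region of interest, micrometres.
#' @param axial_sd_um standard deviation of the focal-plane intensity
#'   envelope along z, micrometres.
#' @param supersample integer rendering supersampling factor.
#' @param seed integer; identical parameters and seed give bit-identical
#'   output.
#'
#' @return an object of class `synth_params` (validated named list).
#' @examples
#' p <- synth_params(effacement = 0.7, seed = 42)
#' p$effacement
#' @export
synth_params <- function(field_size_px = c(160L, 160L),
                         pixel_size_um = 1 / 5.853,
                         n_z = 21L,
                         z_step_um = 0.2,
                         effacement = 0,
                         slit_spacing_um = 0.58,
                         meander_amplitude_um = 0.25,
                         meander_wavelength_um = 1.4,
                         cldn5_basal_coverage = 0.2,
                         cldn5_coupling_exponent = 1,
                         cldn5_segment_um = 1.0,
                         nephrin_gap_fraction_max = 0.5,
                         nephrin_gap_segment_um = 2.0,
                         psf_fwhm_um = 0.115,
                         photon_scale = 200,
                         read_noise_sd = 0.02,
                         endothelial_clutter = TRUE,
                         roi_margin_um = 2,
                         axial_sd_um = 0.35,
                         supersample = 4L,
                         seed = 1L) {
  if (length(field_size_px) != 2L || any(field_size_px < 8)) {
    stop("`field_size_px` must be two integers >= 8", call. = FALSE)
  }
  stop_if_not_scalar_number(pixel_size_um, "pixel_size_um", min = 1e-6)
  stop_if_not_scalar_number(n_z, "n_z", min = 1)
  stop_if_not_scalar_number(z_step_um, "z_step_um", min = 1e-6)
  stop_if_not_scalar_number(effacement, "effacement", min = 0, max = 1)
  stop_if_not_scalar_number(slit_spacing_um, "slit_spacing_um", min = 1e-3)
  stop_if_not_scalar_number(meander_amplitude_um, "meander_amplitude_um", min = 0)
  stop_if_not_scalar_number(meander_wavelength_um, "meander_wavelength_um", min = 1e-3)
  stop_if_not_scalar_number(cldn5_basal_coverage, "cldn5_basal_coverage",
                            min = 0, max = 1)
  stop_if_not_scalar_number(cldn5_coupling_exponent, "cldn5_coupling_exponent",
                            min = 1e-6)
  stop_if_not_scalar_number(cldn5_segment_um, "cldn5_segment_um", min = 1e-3)
  if (nephrin_gap_fraction_max >= 1) {
    stop("`nephrin_gap_fraction_max` must be in [0, 1)", call. = FALSE)
  }
  stop_if_not_scalar_number(nephrin_gap_fraction_max, "nephrin_gap_fraction_max",
                            min = 0, max = 1)
  stop_if_not_scalar_number(nephrin_gap_segment_um, "nephrin_gap_segment_um",
                            min = 1e-3)
  stop_if_not_scalar_number(psf_fwhm_um, "psf_fwhm_um", min = 1e-6)
  stop_if_not_scalar_number(photon_scale, "photon_scale", min = 1e-6,
                            allow_inf = TRUE)
  stop_if_not_scalar_number(read_noise_sd, "read_noise_sd", min = 0)
  stopifnot(is.logical(endothelial_clutter), length(endothelial_clutter) == 1L)
  stop_if_not_scalar_number(roi_margin_um, "roi_margin_um", min = 0)
  stop_if_not_scalar_number(axial_sd_um, "axial_sd_um", min = 1e-3)
  stop_if_not_scalar_number(supersample, "supersample", min = 1)
  stop_if_not_scalar_number(seed, "seed", min = -2^31, max = 2^31)

  p <- list(
    field_size_px = as.integer(field_size_px),
    pixel_size_um = pixel_size_um,
    n_z = as.integer(n_z),
    z_step_um = z_step_um,
    effacement = effacement,
    slit_spacing_um = slit_spacing_um,
    meander_amplitude_um = meander_amplitude_um,
    meander_wavelength_um = meander_wavelength_um,
    cldn5_basal_coverage = cldn5_basal_coverage,
    cldn5_coupling_exponent = cldn5_coupling_exponent,
    cldn5_segment_um = cldn5_segment_um,
    nephrin_gap_fraction_max = nephrin_gap_fraction_max,
    nephrin_gap_segment_um = nephrin_gap_segment_um,
    psf_fwhm_um = psf_fwhm_um,
    photon_scale = photon_scale,
    read_noise_sd = read_noise_sd,
    endothelial_clutter = endothelial_clutter,
    roi_margin_um = roi_margin_um,
    axial_sd_um = axial_sd_um,
    supersample = as.integer(supersample),
    seed = as.integer(seed)
  )
  class(p) <- "synth_params"
  p
}

#' @export
print.synth_params <- function(x, ...) {
  cat("synth_params:",
      sprintf("%d x %d px @ %.4f um/px, %d z-slices (%.2f um)",
              x$field_size_px[1], x$field_size_px[2], x$pixel_size_um,
              x$n_z, x$z_step_um), "\n")
  cat(sprintf("  effacement e = %.2f; spacing %.2f um, amplitude %.2f um\n",
              x$effacement, x$slit_spacing_um * (1 + x$effacement),
              x$meander_amplitude_um * (1 - x$effacement)))
  cat(sprintf("  CLDN5 coverage c(e) = %.2f; nephrin gap fraction g(e) = %.2f\n",
              cldn5_coverage_at(x), nephrin_gap_at(x)))
  invisible(x)
}

# Closed-form coverage / gap laws, exposed for tests and documentation.
cldn5_coverage_at <- function(p) {
  p$cldn5_basal_coverage +
    (1 - p$cldn5_basal_coverage) * p$effacement^p$cldn5_coupling_exponent
}

nephrin_gap_at <- function(p) {
  p$nephrin_gap_fraction_max * max(0, 2 * p$effacement - 1)
}
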