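# CLDN5/nephrin ratio, FSD, phase classification, per-ROI measurement and
# per-glomerulus aggregation.

test_that("area ratio matches brute-force pixel counting", {
  g <- matrix(FALSE, 20, 20)
  roi <- rect_roi(-0.4, -0.4, 19.3, 19.3)
  # identical masks -> ratio 1; empty numerator -> 0
  g[5:10, 5:15] <- TRUE
  expect_equal(cldn5_nephrin_ratio(make_mask(g), make_mask(g), roi), 1.0)
  expect_equal(cldn5_nephrin_ratio(make_mask(matrix(FALSE, 20, 20)),
                                   make_mask(g), roi), 0.0)
  # 30 vs 20 pixels inside the ROI -> 1.5
  gn <- matrix(FALSE, 20, 20); gn[2, 1:20] <- TRUE       # 20 px
  gc <- matrix(FALSE, 20, 20); gc[5:7, 3:12] <- TRUE     # 30 px
  expect_equal(cldn5_nephrin_ratio(make_mask(gc), make_mask(gn), roi), 1.5)
  # nephrin-negative ROI flagged as NA, not an error
  expect_true(is.na(cldn5_nephrin_ratio(make_mask(gc),
                                        make_mask(matrix(FALSE, 20, 20)),
                                        roi)))
  expect_error(cldn5_nephrin_ratio(make_mask(matrix(FALSE, 5, 5)),
                                   make_mask(g), roi), "geometry")
})

test_that("FSD is division with guards", {
  expect_equal(filtration_slit_density(0, 10), 0)
  expect_equal(filtration_slit_density(50, 25), 2.0)
  expect_error(filtration_slit_density(5, 0), "positive")
  expect_error(filtration_slit_density(5, -1), "positive")
})

test_that("phase classification follows the ratio/continuity rules", {
  th <- phase_thresholds(ratio_up = 0.5, continuity_max = 0.1)
  expect_equal(classify_phase(0.1, 0, th), "healthy")
  expect_equal(classify_phase(0.9, 0, th), "phase1")
  expect_equal(classify_phase(1.2, 0.3, th), "phase2")
  # discontinuity dominates even at low ratio
  expect_equal(classify_phase(0.2, 0.5, th), "phase2")
  # boundary: ratio at threshold counts as up-regulated, gaps at threshold do not
  expect_equal(classify_phase(0.5, 0.1, th), "phase1")
  expect_true(is.na(classify_phase(NA_real_, 0, th)))
})

test_that("measuring the same stack twice gives identical records", {
  f <- generate_slit_field(small_params(effacement = 0.4, seed = 9))
  m1 <- measure_area(f$stack, f$roi, sample_id = "s")
  m2 <- measure_area(f$stack, f$roi, sample_id = "s")
  expect_identical(m1, m2)
})

test_that("low-noise measurement recovers ratio and FSD from truth", {
  f <- generate_slit_field(synth_params(effacement = 0, seed = 31,
                                        photon_scale = 2000,
                                        read_noise_sd = 0.005,
                                        endothelial_clutter = FALSE))
  m <- measure_area(f$stack, f$roi, sample_id = "s")
  expect_equal(m$fsd_per_um, analytic_fsd(f$truth), tolerance = 0.10)
  expect_equal(m$ratio, 0.2, tolerance = 0.15)
  expect_equal(m$phase, "healthy")
})

test_that("severe effacement yields phase2 in most areas", {
  f <- generate_slit_field(synth_params(effacement = 1, seed = 17))
  tiles <- tile_rois(f$roi, tile_px = 24L)
  rec <- measure_sample(f$stack, tiles, sample_id = "s")
  phases <- rec$phase[rec$valid]
  expect_gt(mean(phases == "phase2"), 0.5)
})

test_that("continuity index rises with nephrin gap load", {
  idx_at <- function(e, seed) {
    f <- generate_slit_field(small_params(effacement = e, seed = seed,
                                          field_size_px = c(128L, 128L)))
    m <- measure_area(f$stack, f$roi, sample_id = "s")
    m$continuity_gaps_per_um
  }
  lo <- vapply(1:5, function(s) idx_at(0.5, s), numeric(1))   # g = 0
  hi <- vapply(1:5, function(s) idx_at(0.8, s), numeric(1))   # g = 0.3
  expect_gt(median(hi), median(lo))
})

test_that("FSD is invariant to tiling the field 2 x 2", {
  f <- generate_slit_field(small_params(effacement = 0.3, seed = 12,
                                        n_z = 1L, read_noise_sd = 0,
                                        photon_scale = Inf))
  img_n <- f$stack$channels$nephrin[, , 1]
  img_c <- f$stack$channels$cldn5[, , 1]
  big <- channel_stack(
    list(nephrin = array(cbind(rbind(img_n, img_n), rbind(img_n, img_n)),
                         c(2 * dim(img_n), 1)),
         cldn5 = array(cbind(rbind(img_c, img_c), rbind(img_c, img_c)),
                       c(2 * dim(img_c), 1))),
    pixel_size_um = f$stack$pixel_size_um)
  n <- nrow(img_n)
  px <- f$stack$pixel_size_um
  small_roi <- rect_roi(-0.5, -0.5, n - 0.5, n - 0.5, pixel_size_um = px)
  big_roi <- rect_roi(-0.5, -0.5, 2 * n - 0.5, 2 * n - 0.5,
                      pixel_size_um = px)
  # fixed thresholds so both measurements see identical binarization
  cfg <- measure_config(threshold_method = "fixed", fixed_nephrin = 0.3,
                        fixed_cldn5 = 0.3)
  m_small <- measure_area(f$stack, small_roi, cfg, "s")
  m_big <- measure_area(big, big_roi, cfg, "s")
  expect_equal(m_big$roi_area_um2, 4 * m_small$roi_area_um2)
  expect_equal(m_big$fsd_per_um, m_small$fsd_per_um, tolerance = 0.01)
})

test_that("ratio is invariant to uniform intensity rescaling", {
  f <- generate_slit_field(small_params(effacement = 0.5, seed = 14))
  m1 <- measure_area(f$stack, f$roi, sample_id = "s")
  scaled <- channel_stack(lapply(f$stack$channels, function(a) a * 3.7),
                          pixel_size_um = f$stack$pixel_size_um,
                          z_step_um = f$stack$z_step_um)
  m2 <- measure_area(scaled, f$roi, sample_id = "s")
  # Otsu thresholds scale with intensity, so the masks are unchanged
  expect_equal(m2$ratio, m1$ratio, tolerance = 1e-8)
  expect_equal(m2$fsd_per_um, m1$fsd_per_um, tolerance = 1e-8)
})

test_that("estimated FSD tracks truth and ratio rises with effacement", {
  levels <- c(0, 0.25, 0.5, 0.75, 1)
  seeds <- 1:3
  ratio <- numeric(0)
  es <- numeric(0)
  for (e in levels) {
    for (s in seeds) {
      f <- generate_slit_field(synth_params(effacement = e, seed = s,
                                            field_size_px = c(128L, 128L),
                                            n_z = 7L))
      m <- measure_area(f$stack, f$roi, sample_id = "s")
      expect_equal(m$fsd_per_um, analytic_fsd(f$truth), tolerance = 0.15)
      ratio <- c(ratio, m$ratio)
      es <- c(es, e)
    }
  }
  expect_gte(cor(rank(es), rank(ratio)), 0.8)
})

test_that("glomerular summaries follow the minimum-area rule exactly", {
  mk_rec <- function(n, gid = "g1", ratio = 0.5, fsd = 2) {
    data.frame(sample_id = "s", glomerulus_id = gid,
               roi_id = sprintf("r%02d", seq_len(n)),
               nephrin_area_um2 = 1, cldn5_area_um2 = ratio, ratio = ratio,
               l_fs_um = 2, roi_area_um2 = 1, fsd_per_um = fsd,
               phase = "healthy", continuity_gaps_per_um = 0,
               nephrin_threshold = 0.5, cldn5_threshold = 0.5, valid = TRUE,
               stringsAsFactors = FALSE)
  }
  s <- summarize_glomerulus(mk_rec(20))
  expect_equal(s$n_areas, 20L)
  expect_equal(s$mean_ratio, 0.5)

  expect_error(summarize_glomerulus(mk_rec(19)),
               class = "slitmorph_exclusion")
  expect_error(summarize_glomerulus(mk_rec(19)), "g1")

  # invalid records are excluded before counting
  r <- mk_rec(21)
  r$valid[1] <- FALSE
  expect_equal(summarize_glomerulus(r)$n_areas, 20L)

  # mean over 25 known values equals brute-force arithmetic
  set.seed(6)
  r25 <- mk_rec(25)
  r25$ratio <- runif(25)
  r25$fsd_per_um <- runif(25, 0.5, 3)
  s25 <- summarize_glomerulus(r25)
  expect_identical(s25$mean_ratio, sum(r25$ratio) / 25)
  expect_identical(s25$mean_fsd_per_um, sum(r25$fsd_per_um) / 25)

  # batch version collects exclusions instead of failing
  both <- rbind(mk_rec(20, "good"), mk_rec(19, "thin"))
  agg <- summarize_glomeruli(both)
  expect_equal(agg$summaries$glomerulus_id, "good")
  expect_equal(agg$excluded$glomerulus_id, "thin")
  expect_equal(agg$excluded$n_valid, 19L)
})
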