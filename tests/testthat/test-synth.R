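# Synthetic slit-field generator: closed forms, determinism, monotonicity,
# and vector-truth consistency.

test_that("coverage and gap laws pass through at the endpoints", {
  # e = 0: coverage equals the basal fraction exactly, no nephrin gaps
  f <- generate_slit_field(small_params(effacement = 0,
                                        cldn5_basal_coverage = 0.2,
                                        nephrin_gap_fraction_max = 0,
                                        seed = 5))
  expect_equal(f$truth$true_coverage, 0.2, tolerance = 1e-10)
  expect_equal(f$truth$total_slit_length_um, f$truth$base_slit_length_um,
               tolerance = 1e-10)

  # e = 1, gamma = 1, no gaps: continuous claudin-5 lines (coverage 1)
  f1 <- generate_slit_field(small_params(effacement = 1,
                                         cldn5_coupling_exponent = 1,
                                         nephrin_gap_fraction_max = 0,
                                         seed = 5))
  expect_equal(f1$truth$true_coverage, 1.0, tolerance = 1e-10)

  # with gaps, decoration is retained on erased arcs: coverage can exceed 1
  f2 <- generate_slit_field(small_params(effacement = 1,
                                         nephrin_gap_fraction_max = 0.5,
                                         seed = 5))
  expect_equal(f2$truth$true_coverage, 2.0, tolerance = 1e-10)
  expect_equal(f2$truth$total_slit_length_um,
               0.5 * f2$truth$base_slit_length_um, tolerance = 1e-10)
})

test_that("identical parameters and seed give bit-identical output", {
  p <- small_params(effacement = 0.4, seed = 7, endothelial_clutter = TRUE,
                    roi_margin_um = 2)
  f1 <- generate_slit_field(p)
  f2 <- generate_slit_field(p)
  expect_identical(f1$stack, f2$stack)
  expect_identical(f1$truth, f2$truth)
  f3 <- generate_slit_field(small_params(effacement = 0.4, seed = 8,
                                         endothelial_clutter = TRUE,
                                         roi_margin_um = 2))
  expect_false(identical(f1$stack, f3$stack))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_slit_field(small_params(seed = 3)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("truth FSD decreases and coverage increases with effacement", {
  seeds <- 1:10
  levels <- c(0, 0.25, 0.5, 0.75, 1)
  mean_fsd <- numeric(length(levels))
  mean_cov <- numeric(length(levels))
  for (i in seq_along(levels)) {
    tr <- lapply(seeds, function(s) {
      generate_slit_field(small_params(effacement = levels[i], seed = s))$truth
    })
    mean_fsd[i] <- mean(vapply(tr, `[[`, numeric(1), "true_fsd_per_um"))
    mean_cov[i] <- mean(vapply(tr, `[[`, numeric(1), "true_coverage"))
  }
  expect_true(all(diff(mean_fsd) <= 0))
  expect_true(all(diff(mean_cov) >= 0))
  # endpoints strictly ordered
  expect_gt(mean_fsd[1], mean_fsd[length(levels)])
})

test_that("rasterizing truth polylines reproduces the arc length within 3%", {
  f <- generate_slit_field(small_params(effacement = 0.3, seed = 11))
  p <- f$truth$params
  ss <- 4L
  px_ss <- p$pixel_size_um / ss
  d <- slitmorph:::stamp_polylines(f$truth$slit_polylines,
                                   p$field_size_px[1] * ss,
                                   p$field_size_px[2] * ss, px_ss)
  expect_equal(sum(d), f$truth$total_slit_length_um, tolerance = 0.03)
})

test_that("degenerate geometry and invalid parameters are rejected", {
  expect_error(synth_params(effacement = 1.2), "effacement")
  expect_error(synth_params(effacement = -0.1), "effacement")
  expect_error(synth_params(nephrin_gap_fraction_max = 1), "\\[0, 1\\)")
  expect_error(generate_slit_field(
    small_params(slit_spacing_um = 0.1, pixel_size_um = 0.17)),
    "degenerate")
})

test_that("analytic FSD is length over area, with guards", {
  expect_equal(analytic_fsd(list(total_slit_length_um = 50,
                                 roi_area_um2 = 25)), 2.0)
  expect_equal(analytic_fsd(list(total_slit_length_um = 0,
                                 roi_area_um2 = 10)), 0)
  expect_error(analytic_fsd(list(total_slit_length_um = 5,
                                 roi_area_um2 = 0)), "positive")
})

test_that("straight parallel-slit phantom matches the line-count oracle", {
  # amplitude 0, spacing 0.5 um: FSD should be close to 1/s = 2 per um
  f <- generate_slit_field(small_params(effacement = 0,
                                        meander_amplitude_um = 0,
                                        slit_spacing_um = 0.5, seed = 2))
  # independent oracle: count lines x ROI height / ROI area
  v <- f$truth$roi_polygon_px * f$truth$params$pixel_size_um
  w <- max(v[, 1]) - min(v[, 1])
  h <- max(v[, 2]) - min(v[, 2])
  n_lines <- length(unique(vapply(f$truth$slit_polylines,
                                  function(pl) round(pl[1, 1], 6), numeric(1))))
  expect_equal(f$truth$total_slit_length_um, n_lines * h, tolerance = 1e-6)
  expect_equal(f$truth$true_fsd_per_um, n_lines * h / f$truth$roi_area_um2,
               tolerance = 1e-10)
  expect_equal(f$truth$true_fsd_per_um, 2.0, tolerance = 0.1)
})

test_that("cohort generation honors counts, labels, and the master seed", {
  specs <- list(list(label = "control", n = 4L, e_range = c(0, 0.15)),
                list(label = "MCD", n = 5L, e_range = c(0.5, 0.8)),
                list(label = "FSGS", n = 5L, e_range = c(0.5, 0.9)))
  p <- small_params(n_z = 1L)
  cohort <- generate_cohort(specs, seed = 1, params = p)
  expect_length(cohort, 14L)
  labels <- vapply(cohort, `[[`, character(1), "label")
  expect_equal(unname(table(labels)[c("control", "MCD", "FSGS")]),
               c(4L, 5L, 5L), ignore_attr = TRUE)
  es <- vapply(cohort, `[[`, numeric(1), "effacement")
  expect_true(all(es[labels == "control"] <= 0.15))
  expect_true(all(es[labels != "control"] >= 0.5))

  cohort2 <- generate_cohort(specs, seed = 1, params = p)
  expect_identical(cohort, cohort2)

  single <- generate_cohort(list(list(label = "only", n = 1L,
                                      e_range = c(0.2, 0.2))),
                            seed = 3, params = p)
  expect_length(single, 1L)
  expect_equal(single[[1]]$effacement, 0.2)

  expect_error(generate_cohort(list(), seed = 1), "non-empty")
  expect_error(generate_cohort(
    list(list(label = "bad", n = 2L, e_fun = function(n) rep(1.5, n))),
    seed = 1, params = p), "\\[0, 1\\]")
})
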