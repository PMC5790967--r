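test_that("contrast, variability and lung formulas match their definitions", {
  expect_equal(hot_contrast(8, 1, 8), 100)
  expect_equal(hot_contrast(1, 1, 8), 0)
  expect_equal(hot_contrast(6.95, 1, 8), 85)
  expect_error(hot_contrast(2, 1, 1), "exceed 1")
  expect_error(hot_contrast(2, 0, 8), "positive")
  expect_equal(cold_contrast(0, 1), 100)
  expect_equal(cold_contrast(1, 1), 0)
  expect_equal(cold_contrast(0.25, 1), 75)
  expect_error(cold_contrast(-1, 1), "nonnegative")
  expect_equal(background_variability(c(90, 100, 110)), 10)
  expect_equal(background_variability(c(5, 5, 5)), 0)
  expect_error(background_variability(7), "at least 2")
  expect_equal(lung_residual(0, 1), 0)
  expect_equal(lung_residual(0.012, 1), 1.2)
  expect_equal(lung_residual(0.135, 1), 13.5)
  expect_error(lung_residual(1, 0), "positive")
})

test_that("ROI layout gives 60 background samples per size at the sphere diameter", {
  vol <- make_iq_image(1, paper_iq_ratios(c(56, 72, 78, 85)), 0.012)
  rois <- place_rois(vol)
  geom <- vol$geometry
  for (s in seq_len(6)) {
    sp <- rois$spheres[[s]]
    expect_length(sp$background_values, 60) # 12 positions x 5 slices
    expect_equal(sp$diameter_mm, geom$sphere_diameters_mm[s])
    # ROI voxel count consistent with the circle area to within a
    # perimeter's worth of voxels (centres are off-grid in general)
    vs <- vol$voxel_size[1]
    rad <- sp$diameter_mm / 2
    n_area <- pi * rad^2 / vs^2
    expect_lt(abs(length(sp$sphere_values) - n_area), pi * 2 * rad / vs)
  }
  # uniform image: every ROI mean identical
  ratios_flat <- rep(1, 6)
  vol_u <- suppressWarnings(make_iq_image(1, ratios_flat, 1))
  rois_u <- place_rois(vol_u)
  means <- unlist(lapply(rois_u$spheres, function(sp)
    c(mean(sp$sphere_values),
      vapply(sp$background_values, mean, numeric(1)))))
  expect_equal(diff(range(means)), 0, tolerance = 1e-12)
  # ROI clipped by the volume edge is a named error
  vol_small <- vol
  vol_small$voxels <- vol$voxels[1:40, , , drop = FALSE]
  expect_error(place_rois(vol_small), "clipped")
})

test_that("iq_report reproduces requested contrasts and summary means", {
  # PET/MR-style contrasts
  vol_mr <- make_iq_image(1, paper_iq_ratios(c(56, 72, 78, 85)), 0.012)
  rep_mr <- iq_report(vol_mr)
  hot <- rep_mr$spheres[rep_mr$spheres$type == "hot", ]
  expect_equal(hot$contrast_pct, c(56, 72, 78, 85), tolerance = 5e-3)
  expect_equal(rep_mr$mean_hot_contrast_pct, mean(c(56, 72, 78, 85)),
               tolerance = 5e-3)
  expect_equal(rep_mr$lung_residual_pct, 1.2, tolerance = 1e-3)
  # PET/CT-style contrasts: mean of the four printed values is 67.5
  vol_ct <- make_iq_image(1, paper_iq_ratios(c(53, 66, 72, 79)), 0.135)
  rep_ct <- iq_report(vol_ct)
  expect_equal(rep_ct$mean_hot_contrast_pct, 67.5, tolerance = 5e-3)
  expect_equal(rep_ct$lung_residual_pct, 13.5, tolerance = 1e-2)
  # uniform phantom: all contrasts 0, lung residual 100%
  vol_u <- suppressWarnings(make_iq_image(1, rep(1, 6), 1))
  rep_u <- iq_report(vol_u)
  expect_equal(rep_u$spheres$contrast_pct, rep(0, 6), tolerance = 1e-12)
  expect_equal(rep_u$lung_residual_pct, 100, tolerance = 1e-12)
})

test_that("metrics are invariant under global intensity scaling and monotone", {
  vol <- make_iq_image(1, paper_iq_ratios(c(56, 72, 78, 85)), 0.012)
  rep1 <- iq_report(vol)
  vol$voxels <- vol$voxels * 3.7
  rep2 <- iq_report(vol)
  expect_equal(rep2$spheres$contrast_pct, rep1$spheres$contrast_pct,
               tolerance = 1e-12)
  expect_equal(rep2$lung_residual_pct, rep1$lung_residual_pct,
               tolerance = 1e-12)
  # Q_H increases with C_H; Q_C decreases with C_C
  expect_true(all(diff(hot_contrast(c(2, 4, 6), 1, 8)) > 0))
  expect_true(all(diff(cold_contrast(c(0.2, 0.4, 0.6), 1)) < 0))
  # N = 0 iff all background means equal
  expect_identical(background_variability(rep(3, 10)) == 0, TRUE)
  expect_gt(background_variability(c(3, 3.01, 3)), 0)
})

test_that("voxel noise produces the predicted background variability", {
  # per-voxel CV chosen so a 10 mm ROI (n voxels) targets ~7.8%
  vs <- 2
  g <- expand.grid(x = seq(-10, 10) * vs, y = seq(-10, 10) * vs)
  n10 <- sum(g$x^2 + g$y^2 <= 25)
  cv_vox <- 0.078 * sqrt(n10)
  vals <- vapply(1:4, function(s) {
    vol <- make_iq_image(1, paper_iq_ratios(c(56, 72, 78, 85)), 0.012,
                         noise_cv_voxel = cv_vox, seed = s)
    rep <- iq_report(vol)
    rep$spheres$background_variability_pct[1]
  }, numeric(1))
  # sampling error of a CV over 60 ROI means is ~ cv/sqrt(2*59) ~ 0.7
  expect_equal(mean(vals), 7.8, tolerance = 0.15)
})
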