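test_that("locate_peak refines to sub-voxel precision", {
  # centered on a voxel: exact voxel-centre coordinates
  v <- make_point_source_volume(c(0, 0, 0), c(4, 4, 4), 1, 1000)
  expect_equal(locate_peak(v), c(0, 0, 0), tolerance = 1e-9)
  # source at nominal (10, 0, 0), no reconstruction offset: deviation 0
  v10 <- make_point_source_volume(c(10, 0, 0), c(4.8, 4.8, 5.3), 1, 1e5)
  expect_equal(locate_peak(v10) - v10$nominal_position, c(0, 0, 0),
               tolerance = 1e-6)
  # off-grid centre recovered within 0.05 voxel (oracle: the analytic
  # Gaussian's true maximum IS the requested centre)
  voff <- make_point_source_volume(c(10.3, -0.3, 0.3), c(4, 4, 4), 1, 1e5)
  expect_lt(max(abs(locate_peak(voff) - c(10.3, -0.3, 0.3))), 0.05)
  # maximum on the border is an error
  vb <- list(voxels = array(0, c(5, 5, 5)), voxel_size = c(1, 1, 1))
  vb$voxels[1, 3, 3] <- 1
  expect_error(locate_peak(vb), "border")
})

test_that("profile_width matches exact and analytic cases", {
  # triangle peaking at 100, reaching 0 at +/-10 mm: FWHM exactly 10
  x <- seq(-15, 15, by = 1)
  tri <- pmax(0, 100 * (1 - abs(x) / 10))
  expect_equal(profile_width(tri, 1), 10, tolerance = 1e-9)
  expect_equal(profile_width(tri, 1, interp = "linear"), 10,
               tolerance = 1e-9)
  # finely sampled Gaussian with sigma = 2.038 mm: FWHM 4.8 mm within 1%
  g <- gaussian_profile(2.038 * 2 * sqrt(2 * log(2)), 0.25)
  expect_equal(profile_width(g$y, 0.25), 4.8, tolerance = 0.011)
  # FWTM/FWHM for a Gaussian: sqrt(ln 10 / ln 2), oracle via dense widths
  ratio_oracle <- dense_width_oracle(4.8, 0.1) / dense_width_oracle(4.8, 0.5)
  expect_equal(ratio_oracle, sqrt(log(10) / log(2)), tolerance = 1e-9)
  meas_ratio <- profile_width(g$y, 0.25, 0.1) / profile_width(g$y, 0.25, 0.5)
  expect_equal(meas_ratio, ratio_oracle, tolerance = 0.02)
  # truncated profile raises
  expect_error(profile_width(g$y[g$x < 2], 0.25), "truncated")
})

test_that("width recovery stays within 2% over the sampling-adequate grid", {
  for (fwhm in c(3, 4, 4.8, 5.3, 6, 8)) {
    for (vox in c(1, 2)) {
      if (fwhm < 2.4 * vox) next # below NEMA sampling adequacy
      for (off in c(-0.4, 0, 0.4)) {
        g <- gaussian_profile(fwhm, vox, center = off * vox)
        expect_equal(profile_width(g$y, vox), fwhm, tolerance = 0.02,
                     label = sprintf("FWHM %.1f mm at voxel %.0f mm, offset %.1f",
                                     fwhm, vox, off))
        expect_equal(profile_width(g$y, vox, 0.1), 1.82263 * fwhm,
                     tolerance = 0.02)
      }
    }
  }
})

test_that("resolution report recovers true widths and respects invariances", {
  vols <- list(
    make_point_source_volume(c(10, 0, 0), c(4.4, 4.1, 5.3), 1, 1e5,
                             label = "1 cm"),
    make_point_source_volume(c(100, 0, 0), c(5.1, 4.8, 5.8), 1, 1e5,
                             label = "10 cm radial offset")
  )
  rep <- resolution_report(vols)
  expect_s3_class(rep, "resolution_report")
  expect_equal(nrow(rep), 6)
  r1 <- rep[rep$position == "1 cm", ]
  expect_equal(r1$fwhm_mm[r1$direction == "radial"], 4.4, tolerance = 0.01)
  expect_equal(r1$fwhm_mm[r1$direction == "tangential"], 4.1,
               tolerance = 0.01)
  expect_equal(r1$fwhm_mm[r1$direction == "axial"], 5.3, tolerance = 0.01)
  # FWTM >= FWHM everywhere; Gaussian ratio 1.823 +/- 2%
  expect_true(all(rep$fwtm_mm >= rep$fwhm_mm))
  expect_equal(rep$fwtm_mm / rep$fwhm_mm, rep(1.82263, 6), tolerance = 0.02)
  # isotropic source: all three directions equal
  iso <- resolution_report(make_point_source_volume(c(10, 0, 0), rep(5, 3),
                                                    1, 1e5))
  expect_equal(diff(range(iso$fwhm_mm)), 0, tolerance = 1e-6)
  # amplitude scaling leaves widths unchanged
  v2 <- vols[[1]]
  v2$voxels <- v2$voxels * 7.3
  expect_equal(resolution_report(v2)$fwhm_mm, r1$fwhm_mm, tolerance = 1e-12)
  expect_error(resolution_report(list()), "no point-source volumes")
})

test_that("a source offset along y maps y to the radial direction", {
  v <- make_point_source_volume(c(0, 100, 0), c(5.5, 4.5, 5.0), 1, 1e5)
  rep <- resolution_report(v)
  # fwhm_true is (radial, tangential, axial) = (y, x, z) for this source
  expect_equal(rep$fwhm_mm[rep$direction == "radial"], 4.5, tolerance = 0.01)
  expect_equal(rep$fwhm_mm[rep$direction == "tangential"], 5.5,
               tolerance = 0.01)
})
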