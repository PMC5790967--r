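test_that("phantom geometry validates its invariants", {
  geom <- phantom_geometry()
  expect_s3_class(geom, "phantom_geometry")
  expect_equal(scatter_phantom_volume_mL(geom), pi * 10.15^2 * 70)
  expect_error(phantom_geometry(cylinder_outer_diameter_mm = -1), "positive")
  expect_error(phantom_geometry(sleeve_inner_diameters_mm = c(5, 6, 7)),
               "equal length|5 sleeves")
  expect_error(phantom_geometry(iq_sphere_diameters_mm = c(10, 9, 17, 22, 28, 37)),
               "increasing")
})

test_that("point-source volumes hold the requested Gaussian", {
  vol <- make_point_source_volume(c(10, 0, 0), c(4.8, 4.8, 5.3), 1, 1e5)
  # counts matched to 0.1%
  expect_equal(sum(vol$voxels), 1e5, tolerance = 1e-3)
  # symmetric Gaussian at the origin peaks at the origin voxel
  v0 <- make_point_source_volume(c(0, 0, 0), c(4, 4, 4), 1, 1000)
  d <- dim(v0$voxels)
  expect_equal(as.integer(arrayInd(which.max(v0$voxels), d)),
               as.integer((d + 1) / 2))
  # generated profile width matches the dense analytic oracle within 1%
  idx <- arrayInd(which.max(vol$voxels), dim(vol$voxels))
  prof <- vol$voxels[, idx[2], idx[3]]
  expect_equal(profile_width(prof, 1), dense_width_oracle(4.8),
               tolerance = 0.01)
  expect_error(make_point_source_volume(c(0, 0, 0), c(4, 4, 4), -1, 10),
               "invalid geometry")
  expect_warning(make_point_source_volume(c(0, 0, 0), c(3, 3, 3), 2, 10),
                 "sampling")
})

test_that("sleeve series follows the attenuation and decay model", {
  starts <- seq(0, 1200, by = 300)
  # no attenuation: all decay-corrected rates equal S0
  acq0 <- make_sleeve_series(22.2, 0, 5000, 60, starts)
  r0 <- decay_corrected_rate(acq0$sleeves$counts, acq0$sleeves$start_s,
                             acq0$sleeves$duration_s, 5000)
  expect_equal(r0, rep(22.2, 5), tolerance = 1e-12)
  # positive attenuation: raw rates strictly decreasing in sleeve index
  acq <- make_sleeve_series(22.2, 0.05, 5000, 60, rep(0, 5))
  expect_true(all(diff(acq$sleeves$counts) < 0))
  expect_error(make_sleeve_series(22.2, 0.05, -5, 60, starts), "positive")
  expect_true(is.list(acq$ground_truth))
})

test_that("count-rate series conserves counts and matches its model", {
  acq <- small_countrate(n_frames = 10)
  m <- calibrate_countrate_model(0.434, 218, 17.7)
  cal <- acq$calibration
  for (i in c(1, 5, 10)) {
    f <- acq$frames[[i]]
    a <- cal$A0_MBq * decay_factor(f$start_s + f$duration_s / 2 - cal$t0_s)
    expected <- (trues_rate(m, a) + scatter_rate(m, a) + randoms_rate(m, a)) *
      f$duration_s
    # direct summation of the masked collapsed per-slice profiles
    prof <- mask_beyond_12cm(align_and_collapse(f$sino), cal$bin_size_mm)
    expect_equal(sum(prof) * f$n_slices, expected, tolerance = 1e-3)
  }
  expect_error(
    make_countrate_series(calibrate_countrate_model(0.4, 218, 17.7),
                          n_bins = 64, bin_size_mm = 2),
    "120 mm")
})

test_that("decay halves activity over one half-life (schedule invariant)", {
  sched <- countrate_schedule(initial_activity_MBq = 1000,
                              end_activity_MBq = 2, knee_activity_MBq = 60,
                              n_frames = 12)
  a_fun <- function(t) 1000 * decay_factor(t)
  expect_equal(a_fun(sched$t_mid_s + F18_HALF_LIFE_S),
               sched$activity_MBq / 2, tolerance = 1e-12)
  # schedule spans high to low and is time-ordered
  expect_true(all(diff(sched$t_mid_s) > 0))
  expect_true(all(diff(sched$activity_MBq) < 0))
})

test_that("Poisson mode is reproducible under a fixed seed", {
  a1 <- small_countrate(n_frames = 6, n_slices = 2, noise = "poisson",
                        seed = 7)
  a2 <- small_countrate(n_frames = 6, n_slices = 2, noise = "poisson",
                        seed = 7)
  a3 <- small_countrate(n_frames = 6, n_slices = 2, noise = "poisson",
                        seed = 8)
  expect_identical(a1$frames[[3]]$slices, a2$frames[[3]]$slices)
  expect_false(identical(a1$frames[[3]]$slices, a3$frames[[3]]$slices))
})

test_that("IQ image reproduces requested ratios and validates inputs", {
  ratios <- paper_iq_ratios(c(56, 72, 78, 85))
  vol <- make_iq_image(1, ratios, 0.012)
  rois <- place_rois(vol)
  for (s in seq_len(6)) {
    C_B <- mean(vapply(rois$spheres[[s]]$background_values, mean, numeric(1)))
    measured <- mean(rois$spheres[[s]]$sphere_values) / C_B
    expect_equal(measured, ratios[s], tolerance = 5e-3)
  }
  expect_error(make_iq_image(1, ratios, -0.1), "nonnegative")
  expect_error(make_iq_image(1, ratios[1:5] * 0 - 1, 0.1), "6|positive")
  expect_error(make_iq_image(1, ratios, 0.1, voxel_size_mm = 5), "1/3")
  expect_true(is.list(vol$ground_truth))
})
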