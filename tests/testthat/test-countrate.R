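test_that("align_and_collapse centres projections and conserves counts", {
  n <- 32
  c0 <- floor(n / 2) + 1
  base <- dnorm(seq_len(n), mean = c0, sd = 2)
  # single projection already centered: identity
  expect_equal(align_and_collapse(matrix(base, ncol = 1)), base)
  # peak displaced +3 bins: realigned, sum unchanged
  shifted <- c(base[(n - 2):n], base[1:(n - 3)])
  out <- align_and_collapse(matrix(shifted, ncol = 1))
  expect_equal(out, base)
  expect_equal(sum(out), sum(shifted))
  # multi-angle sum conserves total counts exactly
  sino <- cbind(base, shifted, rev(base))
  expect_equal(sum(align_and_collapse(sino)), sum(sino))
  # all-zero projection skipped with a record
  sino0 <- cbind(base, 0)
  out0 <- align_and_collapse(sino0)
  expect_equal(attr(out0, "skipped_angles"), 2L)
})

test_that("the 12 cm mask keeps exactly the bins with |r| <= 120 mm", {
  # flat profile, 256 bins at 2 mm: 121 retained bin centres
  prof <- rep(1, 256)
  masked <- mask_beyond_12cm(prof, 2)
  expect_equal(sum(masked != 0), 121)
  expect_lte(sum(masked), sum(prof))
  # counts already inside the mask: identity
  inside <- numeric(256)
  inside[120:140] <- 5
  expect_equal(mask_beyond_12cm(inside, 2), inside)
  expect_error(mask_beyond_12cm(rep(1, 20), 2), "extent")
})

test_that("trues/background split matches its contract", {
  n <- 256
  r <- (seq_len(n) - 1 - floor(n / 2)) * 2
  # pure flat background: trues = 0
  flat <- mask_beyond_12cm(rep(3, n), 2)
  sp <- split_trues_background(flat, 2)
  expect_equal(unname(sp["trues"]), 0, tolerance = 1e-12)
  expect_equal(unname(sp["background"]), sum(flat), tolerance = 1e-12)
  # narrow unit-area peak on zero background: trues = 1, background = 0
  peak <- numeric(n)
  peak[r == 0] <- 1
  sp2 <- split_trues_background(peak, 2)
  expect_equal(unname(sp2["trues"]), 1, tolerance = 1e-12)
  expect_equal(unname(sp2["background"]), 0, tolerance = 1e-12)
  # count conservation: trues + background = masked total, exactly,
  # over randomly generated peak+pedestal profiles
  set.seed(3)
  for (i in 1:20) {
    prof <- mask_beyond_12cm(
      abs(rnorm(n, 10)) + 100 * dnorm(r, 0, runif(1, 3, 10)), 2)
    spl <- split_trues_background(prof, 2)
    expect_equal(unname(spl["trues"] + spl["background"]), sum(prof),
                 tolerance = 1e-12)
  }
})

test_that("curves reproduce the generating model frame by frame", {
  acq <- small_countrate(n_frames = 12)
  cv <- compute_curves(acq)
  m <- calibrate_countrate_model(0.434, 218, 17.7)
  fr <- cv$frames
  a <- fr$activity_MBq
  expect_equal(fr$T_kcps * 1000, trues_rate(m, a), tolerance = 1e-9)
  expect_equal(fr$S_kcps * 1000, scatter_rate(m, a), tolerance = 1e-6)
  expect_equal(fr$R_kcps * 1000, randoms_rate(m, a), tolerance = 1e-9)
  # NECR column is T^2/(T+S+R) of the measured columns
  expect_equal(fr$NECR_kcps,
               fr$T_kcps^2 / (fr$T_kcps + fr$S_kcps + fr$R_kcps),
               tolerance = 1e-12)
  # and NECR <= T framewise
  expect_true(all(fr$NECR_kcps <= fr$T_kcps + 1e-12))
  expect_equal(cv$summary$SF_reported_pct, 43.4, tolerance = 1e-6)
})

test_that("SF is invariant to frame-duration rescaling and NECR scales with efficiency", {
  cv1 <- compute_curves(small_countrate(n_frames = 10))
  cv2 <- compute_curves(small_countrate(n_frames = 10,
                                        frame_duration_s = 300))
  expect_equal(cv2$summary$SF_reported_pct, cv1$summary$SF_reported_pct,
               tolerance = 1e-9)
  # global efficiency multiplier c on all emitted counts scales NECR by c
  acq <- small_countrate(n_frames = 10)
  cc <- 1.7
  acq$frames <- lapply(acq$frames, function(f) {
    f$sino <- f$sino * cc
    f
  })
  acq$calibration$delayed_counts <- acq$calibration$delayed_counts * cc
  cv3 <- compute_curves(acq)
  cv0 <- compute_curves(small_countrate(n_frames = 10))
  expect_equal(cv3$frames$NECR_kcps, cc * cv0$frames$NECR_kcps,
               tolerance = 1e-9)
  expect_equal(cv3$summary$SF_reported_pct, cv0$summary$SF_reported_pct,
               tolerance = 1e-9)
})

test_that("model-subtraction randoms agree with the delayed channel", {
  acq <- small_countrate(n_frames = 12)
  cv_d <- compute_curves(acq, randoms_source = "delayed-provided")
  cv_m <- compute_curves(acq, randoms_source = "model-subtraction")
  expect_equal(cv_m$summary$SF_reported_pct, cv_d$summary$SF_reported_pct,
               tolerance = 0.01)
  expect_equal(cv_m$frames$NECR_kcps, cv_d$frames$NECR_kcps,
               tolerance = 0.02)
})

test_that("find_necr_peak refines the vertex and detects monotone curves", {
  # symmetric parabola sampled at 3 of its points: exact vertex
  fake <- list(frames = data.frame(
    frame = 1:5,
    activity_conc_kBq_cc = c(1, 2, 3, 4, 5),
    NECR_kcps = 100 - (c(1, 2, 3, 4, 5) - 3.3)^2 * 4
  ))
  pk <- find_necr_peak(fake)
  expect_equal(pk$a_at_peak_kBq_cc, 3.3, tolerance = 1e-12)
  expect_equal(pk$NECR_peak_kcps, 100, tolerance = 1e-12)
  # refined peak value >= max sampled frame value (brute-force comparison)
  cv <- compute_curves(small_countrate(n_frames = 15))
  pk2 <- find_necr_peak(cv)
  expect_gte(pk2$NECR_peak_kcps, max(cv$frames$NECR_kcps))
  # monotone curve: no-peak error
  mono <- list(frames = data.frame(frame = 1:6,
                                   activity_conc_kBq_cc = 1:6,
                                   NECR_kcps = (1:6)^1.5))
  expect_error(find_necr_peak(mono), "no-peak|monotone")
  expect_error(find_necr_peak(list(frames = fake$frames[1:4, ])), "5 frames")
})

test_that("randoms accuracy reports the injected count-loss bias", {
  # unbiased noise-free fixture: 0% everywhere
  cv0 <- compute_curves(small_countrate(n_frames = 15))
  acc0 <- randoms_accuracy(cv0)
  expect_equal(acc0$max_abs_pct_error_below_peak, 0, tolerance = 1e-9)
  # injected maxima are recovered within 0.1 points
  model <- calibrate_countrate_model(0.434, 218, 17.7)
  op <- attr(model, "operating_point")
  sched <- countrate_schedule()
  for (mb in c(3.4, 3.1)) {
    bias <- make_bias_profile(mb, sched$activity_MBq, op$a_peak_MBq)
    acq <- make_countrate_series(model, n_slices = 2, n_angles = 32,
                                 bias_profile = bias)
    acc <- randoms_accuracy(compute_curves(acq))
    expect_equal(acc$max_abs_pct_error_below_peak, mb, tolerance = 0.1 / mb)
  }
  # per-slice errors agree with the frame-level ones for uniform slices
  accs <- randoms_accuracy(cv0, per_slice = TRUE)
  expect_equal(dim(accs$slice_pct_error), c(15, 3))
  expect_equal(max(abs(accs$slice_pct_error)), 0, tolerance = 1e-9)
})

test_that("Poisson-mode estimates stay within 3 MC standard errors of truth", {
  sf_hat <- a_hat <- numeric(12)
  for (k in seq_len(12)) {
    acq <- small_countrate(n_frames = 12, n_slices = 2, noise = "poisson",
                           seed = 100 + k, frame_duration_s = 10)
    cv <- compute_curves(acq)
    sf_hat[k] <- cv$summary$SF_reported_pct
  }
  se <- sd(sf_hat) / sqrt(length(sf_hat))
  expect_lt(abs(mean(sf_hat) - 43.4), 3 * se + 1e-6)
})
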