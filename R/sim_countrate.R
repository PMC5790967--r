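#' Decay schedule for a count-rate acquisition
#'
#' Frame mid-time activities for a decaying line-source acquisition, in two
#' log-spaced phases: a dense phase from the starting activity down to
#' `knee_activity_MBq` (bracketing the expected NECR peak with closely
#' spaced frames, as is common practice so the peak is well resolved), and a
#' sparser phase down to `end_activity_MBq` supplying the low-activity
#' frames used for the scatter-fraction average and the count-loss
#' extrapolation.
#'
#' @param initial_activity_MBq activity at the start of the series.
#' @param end_activity_MBq activity at the last frame mid-time.
#' @param knee_activity_MBq boundary between the two phases.
#' @param n_frames total number of frames.
#' @param dense_frac fraction of frames in the dense (high-activity) phase.
#' @param half_life_s isotope half-life.
#' @return data frame with `activity_MBq` and `t_mid_s` (mid-times from the
#'   activity reference time).
#' @export
countrate_schedule <- function(initial_activity_MBq = 1295,
                               end_activity_MBq = 1.8,
                               knee_activity_MBq = 80,
                               n_frames = 30,
                               dense_frac = 2 / 3,
                               half_life_s = F18_HALF_LIFE_S) {
  stopifnot(initial_activity_MBq > knee_activity_MBq,
            knee_activity_MBq > end_activity_MBq,
            end_activity_MBq > 0, n_frames >= 5)
  n1 <- max(2L, round(dense_frac * n_frames))
  n2 <- n_frames - n1
  a1 <- initial_activity_MBq *
    (knee_activity_MBq / initial_activity_MBq)^((seq_len(n1) - 1) / (n1 - 1))
  a2 <- knee_activity_MBq *
    (end_activity_MBq / knee_activity_MBq)^(seq_len(n2) / n2)
  a <- c(a1, a2)
  data.frame(activity_MBq = a,
             t_mid_s = log2(initial_activity_MBq / a) * half_life_s)
}

#' Simulate the line-in-cylinder count-rate acquisition
#'
#' Generates the input of the scatter-fraction / NECR / accuracy tests: a
#' time-ordered series of frames, each holding per-slice sinograms of a line
#' source at the 45 mm offset inside the scatter cylinder. Each projection
#' is composed of a narrow trues peak (6 mm FWHM kernel at the projected
#' line position), a broad scatter background (Gaussian, 60 mm FWHM, under
#' the peak), and a flat randoms floor. Activity decays with the isotope
#' half-life; trues follow the paralyzable dead-time model, scatter is a
#' fixed fraction of trues, randoms grow quadratically
#' (see [countrate_model()]).
#'
#' Because the scatter fraction is operationally defined by the NU2
#' estimator (12 cm mask, +/-2 cm under-peak interpolation), the generator
#' calibrates the raw trues/scatter amplitudes through the estimator's
#' response to the two kernel shapes (a 2x2 linear solve, computed once per
#' geometry), so that the estimator-referenced trues and scatter rates equal
#' the model's exactly in noise-free mode. The randoms floor is flat across
#' the whole radial extent (hence invariant under profile alignment) with
#' its level set so that the randoms inside the 12 cm mask equal the model
#' rate; the same value is recorded as the per-frame delayed channel.
#'
#' The acquisition also records the dead-time constant used, emulating the
#' scanner's built-in count-loss correction. `bias_profile` multiplies the
#' emitted trues (scatter scales with them, so the scatter fraction is
#' unaffected), emulating an imperfect correction: [randoms_accuracy()]
#' then reports exactly the injected deviation.
#'
#' @param model a [countrate_model()], typically from
#'   [calibrate_countrate_model()].
#' @param initial_activity_MBq,end_activity_MBq,knee_activity_MBq,n_frames
#'   schedule parameters, see [countrate_schedule()].
#' @param n_slices slices per frame.
#' @param n_bins,n_angles,bin_size_mm sinogram geometry; the radial grid
#'   must cover +/-120 mm.
#' @param frame_duration_s duration of every frame.
#' @param noise `"none"` for expectation values (slices stored once and
#'   shared), `"poisson"` for per-slice counting noise (full 3-D arrays;
#'   memory scales with `n_frames * n_slices * n_bins * n_angles`).
#' @param bias_profile `NULL`, or per-frame trues multipliers (length
#'   `n_frames`), e.g. from [make_bias_profile()].
#' @param seed RNG seed for `noise = "poisson"`.
#' @param phantom a [phantom_geometry()].
#' @param phantom_volume_mL activity-concentration denominator.
#' @return object of class `countrate_acquisition`: `frames` (list of
#'   `start_s`, `duration_s`, and either `sino` + `n_slices` or a 3-D
#'   `slices` array), `calibration` (`A0_MBq`, `t0_s`, `half_life_s`,
#'   `bin_size_mm`, `deadtime_lambda_per_MBq`, `delayed_counts`), `phantom`,
#'   `phantom_volume_mL`, and a `ground_truth` record.
#' @export
make_countrate_series <- function(model,
                                  initial_activity_MBq = 1295,
                                  end_activity_MBq = 1.8,
                                  knee_activity_MBq = 80,
                                  n_frames = 30,
                                  n_slices = 81,
                                  n_bins = 256, n_angles = 128,
                                  bin_size_mm = 2,
                                  frame_duration_s = 120,
                                  noise = c("none", "poisson"),
                                  bias_profile = NULL,
                                  seed = 0,
                                  phantom = phantom_geometry(),
                                  phantom_volume_mL = scatter_phantom_volume_mL(phantom)) {
  noise <- match.arg(noise)
  stopifnot(inherits(model, "countrate_model"), n_slices >= 1)
  r <- .bin_centers(n_bins, bin_size_mm)
  if (max(r) < 120 || min(r) > -120)
    stop("sinogram radial extent must cover +/-120 mm for the 12 cm mask")
  sched <- countrate_schedule(initial_activity_MBq, end_activity_MBq,
                              knee_activity_MBq, n_frames,
                              half_life_s = model$half_life_s)
  if (initial_activity_MBq / end_activity_MBq < 100)
    warning("activity range spans less than 2 decades; ",
            "low-activity frames may not qualify as randoms-free")
  if (!is.null(bias_profile) && length(bias_profile) != n_frames)
    stop("bias_profile must have one trues multiplier per frame")
  bias <- if (is.null(bias_profile)) rep(1, n_frames) else bias_profile

  # per-angle kernels at the projected line position r0(theta)
  theta <- (seq_len(n_angles) - 1) * pi / n_angles
  r0 <- phantom$line_offset_mm * cos(theta)
  sig_t <- 6 / (2 * sqrt(2 * log(2)))
  sig_s <- 60 / (2 * sqrt(2 * log(2)))
  KT <- vapply(r0, function(x) {
    k <- exp(-(r - x)^2 / (2 * sig_t^2)); k / sum(k)
  }, numeric(n_bins))
  KS <- vapply(r0, function(x) {
    k <- exp(-(r - x)^2 / (2 * sig_s^2)); k / sum(k)
  }, numeric(n_bins))
  KT <- KT / n_angles # unit total counts across the slice sinogram
  KS <- KS / n_angles

  # estimator response of the unit kernels (alignment + mask + split),
  # computed once: gives the 2x2 system mapping raw amplitudes to
  # estimator-referenced trues/scatter counts
  mask_split <- function(K) {
    prof <- mask_beyond_12cm(align_and_collapse(K), bin_size_mm)
    .profile_split(prof, r)
  }
  respT <- mask_split(KT)
  respS <- mask_split(KS)
  M <- cbind(respT, respS) # rows: trues, background; cols: raw T, raw S

  n_mask <- sum(abs(r) <= 120)
  sched$a <- sched$activity_MBq
  frames <- vector("list", n_frames)
  delayed <- numeric(n_frames)
  if (noise == "poisson") set.seed(seed)
  for (i in seq_len(n_frames)) {
    a <- sched$a[i]
    d <- frame_duration_s
    C_T <- trues_rate(model, a) * bias[i] * d
    C_S <- scatter_rate(model, a) * bias[i] * d
    C_R <- randoms_rate(model, a) * d
    amp <- solve(M, c(C_T, C_S)) # raw trues/scatter counts for the frame
    if (any(amp < 0))
      stop("amplitude calibration produced negative kernel weights; ",
           "scatter fraction too extreme for the kernel shapes")
    r_level <- C_R / (n_mask * n_angles) # flat floor; mask holds exactly C_R
    sino <- (amp[1] * KT + amp[2] * KS + r_level) / n_slices
    # times shifted by d/2 so the first frame starts at 0; the activity
    # reference time t0 = d/2 keeps frame mid-times on the decay schedule
    st <- sched$t_mid_s[i]
    if (noise == "none") {
      frames[[i]] <- list(start_s = st, duration_s = d,
                          sino = sino, n_slices = n_slices)
    } else {
      sl <- array(stats::rpois(n_bins * n_angles * n_slices, sino),
                  dim = c(n_bins, n_angles, n_slices))
      frames[[i]] <- list(start_s = st, duration_s = d, slices = sl)
    }
    delayed[i] <- C_R
  }
  op <- attr(model, "operating_point")
  gt <- list(
    sf_true_pct = 100 * model$sf_true,
    necr_peak_true_kcps = if (!is.null(op)) op$necr_peak_kcps else NA_real_,
    a_peak_true_kBq_cc = if (!is.null(op)) op$a_peak_kBq_cc else NA_real_,
    c_T = model$c_T, lambda_dt = model$lambda_dt, k_R = model$k_R,
    max_bias_true_pct = 100 * max(abs(bias - 1))
  )
  structure(list(
    frames = frames,
    calibration = list(A0_MBq = initial_activity_MBq,
                       t0_s = frame_duration_s / 2,
                       half_life_s = model$half_life_s,
                       bin_size_mm = bin_size_mm,
                       deadtime_lambda_per_MBq = model$lambda_dt,
                       delayed_counts = delayed),
    phantom = phantom,
    phantom_volume_mL = phantom_volume_mL,
    ground_truth = gt
  ), class = "countrate_acquisition")
}

#' Trues-bias profile peaking below the NECR peak
#'
#' Builds the per-frame trues multipliers used to emulate an imperfect
#' count-loss correction: the fractional bias rises as activity squared up
#' to a reference frame (the highest-activity frame safely below the NECR
#' peak) where it equals `max_bias_pct`, and falls off symmetrically in
#' log-activity above it. The maximum bias over below-peak frames therefore
#' equals `max_bias_pct` exactly.
#'
#' @param max_bias_pct maximum percent deviation of the corrected trues.
#' @param activities_MBq per-frame activities (e.g.
#'   `countrate_schedule()$activity_MBq`).
#' @param a_peak_MBq total activity at the NECR peak (from the model's
#'   operating point).
#' @param margin the reference frame is the largest activity below
#'   `margin * a_peak_MBq`.
#' @return numeric vector of trues multipliers, length
#'   `length(activities_MBq)`.
#' @export
make_bias_profile <- function(max_bias_pct, activities_MBq, a_peak_MBq,
                              margin = 0.95) {
  a_ok <- activities_MBq[activities_MBq < margin * a_peak_MBq]
  if (length(a_ok) == 0L)
    stop("no frame activity lies below the NECR peak")
  a_ref <- max(a_ok)
  rel <- pmin(activities_MBq / a_ref, a_ref / activities_MBq)
  1 + (max_bias_pct / 100) * rel^2
}

#' @export
print.countrate_acquisition <- function(x, ...) {
  nf <- length(x$frames)
  cat("Count-rate acquisition:", nf, "frames\n")
  a <- x$calibration$A0_MBq *
    decay_factor(vapply(x$frames, function(f) f$start_s + f$duration_s / 2,
                        numeric(1)) - x$calibration$t0_s,
                 x$calibration$half_life_s)
  cat(sprintf("  activity %.3g -> %.3g MBq over %.1f h\n",
              max(a), min(a),
              (x$frames[[nf]]$start_s - x$frames[[1]]$start_s) / 3600))
  ns <- if (!is.null(x$frames[[1]]$slices)) dim(x$frames[[1]]$slices)[3]
        else x$frames[[1]]$n_slices
  cat("  slices/frame:", ns, " bin size:", x$calibration$bin_size_mm, "mm\n")
  invisible(x)
}
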