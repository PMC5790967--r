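# Shared fixture builders. Count-rate fixtures for unit tests use reduced
# sinogram sizes (fewer angles/slices); the estimator's amplitude
# calibration makes recovery independent of those sizes in noise-free mode.

small_countrate <- function(sf = 0.434, necr_peak = 218, a_peak = 17.7,
                            n_frames = 30, n_slices = 3, n_angles = 32,
                            bias_profile = NULL, noise = "none", seed = 0,
                            frame_duration_s = 120) {
  model <- calibrate_countrate_model(sf, necr_peak, a_peak)
  make_countrate_series(model, n_frames = n_frames, n_slices = n_slices,
                        n_angles = n_angles, bias_profile = bias_profile,
                        noise = noise, seed = seed,
                        frame_duration_s = frame_duration_s)
}

# dense analytic Gaussian profile, used as the independent width oracle
gaussian_profile <- function(fwhm, spacing, extent = 40, center = 0) {
  x <- seq(-extent, extent, by = spacing)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  list(x = x, y = exp(-(x - center)^2 / (2 * sigma^2)))
}

# brute-force width of a function at a fractional level by dense evaluation
# and sign-change search (independent of profile_width's interpolation)
dense_width_oracle <- function(fwhm, frac = 0.5, center = 0) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  f <- function(x) exp(-(x - center)^2 / (2 * sigma^2)) - frac
  left <- uniroot(f, c(center - 10 * sigma, center), tol = 1e-12)$root
  right <- uniroot(f, c(center, center + 10 * sigma), tol = 1e-12)$root
  right - left
}

paper_iq_ratios <- function(hot_contrasts, cold_contrasts = c(75, 75)) {
  c(ratio_for_hot_contrast(hot_contrasts), ratio_for_cold_contrast(cold_contrasts))
}
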