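# Radial bin-centre coordinates: bin i (1-based) sits at
# (i - 1 - floor(n/2)) * bin_size, so there is a bin exactly at r = 0 and,
# for a 256 x 2 mm grid, exactly 121 bin centres satisfy |r| <= 120 mm.
.bin_centers <- function(n, bin_size_mm) {
  ((seq_len(n) - 1) - floor(n / 2)) * bin_size_mm
}

# trues/background split shared by the analysis and the generator's
# amplitude calibration: pedestal values at +/-`halfwidth` by linear
# interpolation, straight line between them under the peak, trues = excess
# above the line within the window, background = everything else.
# Returns c(trues, background); no clamping here.
.profile_split <- function(profile, r, halfwidth_mm = 20) {
  ped <- stats::approx(r, profile, xout = c(-halfwidth_mm, halfwidth_mm))$y
  if (any(is.na(ped)))
    stop("profile does not cover the +/-", halfwidth_mm, " mm window")
  inpk <- abs(r) <= halfwidth_mm
  line <- ped[1] + (ped[2] - ped[1]) * (r[inpk] + halfwidth_mm) /
    (2 * halfwidth_mm)
  trues <- sum(profile[inpk] - line)
  c(trues = trues, background = sum(profile) - trues)
}

#' Align sinogram projections and collapse to a single profile
#'
#' For each angular projection, circularly shifts the radial bins so that the
#' projection maximum sits at the central (r = 0) bin, then sums the shifted
#' projections over angles. Total counts are conserved exactly. All-zero
#' projections are skipped (left in place, recorded in attribute
#' `"skipped_angles"`).
#'
#' @param slice_sinogram matrix, radial bins x angles.
#' @return numeric vector of length `nrow(slice_sinogram)`: the aligned,
#'   angle-collapsed profile.
#' @export
align_and_collapse <- function(slice_sinogram) {
  stopifnot(is.matrix(slice_sinogram))
  n <- nrow(slice_sinogram)
  c0 <- floor(n / 2) + 1L # bin at r = 0
  colmax <- apply(slice_sinogram, 2, max)
  skipped <- unname(which(colmax <= 0))
  shifts <- c0 - apply(slice_sinogram, 2, which.max)
  shifts[skipped] <- 0L
  idx <- outer(seq_len(n), shifts, function(i, s) ((i - 1 - s) %% n) + 1L)
  shifted <- matrix(slice_sinogram[cbind(as.vector(idx),
                                         rep(seq_along(shifts), each = n))],
                    nrow = n)
  out <- rowSums(shifted)
  if (length(skipped)) attr(out, "skipped_angles") <- skipped
  out
}

#' Zero the profile beyond a 12 cm radius
#'
#' @param profile aligned collapsed profile (vector).
#' @param bin_size_mm radial bin pitch.
#' @param radius_mm mask radius (120 mm per the NU2 procedure).
#' @return profile with bins at `|r| > radius_mm` set to zero.
#' @export
mask_beyond_12cm <- function(profile, bin_size_mm, radius_mm = 120) {
  r <- .bin_centers(length(profile), bin_size_mm)
  if (max(r) < radius_mm || min(r) > -radius_mm)
    stop("sinogram radial extent (", min(r), " to ", max(r),
         " mm) does not cover +/-", radius_mm, " mm")
  profile[abs(r) > radius_mm] <- 0
  profile
}

#' Split a masked profile into trues and background counts
#'
#' Reads pedestal values at -20 and +20 mm (linear interpolation between the
#' straddling bins), draws a straight line between them under the line-source
#' peak, and counts the excess above the line within the +/-20 mm window as
#' trues. Background is everything else inside the mask, including the
#' under-peak trapezoid. Trues + background equals the masked total exactly
#' (before clamping).
#'
#' @param profile aligned, masked profile.
#' @param bin_size_mm radial bin pitch.
#' @param halfwidth_mm half-width of the under-peak window (20 mm).
#' @return named vector `c(trues, background)`; if the trues come out
#'   negative they are clamped to zero (flagged via attribute `"clamped"`)
#'   and the background absorbs the difference.
#' @export
split_trues_background <- function(profile, bin_size_mm, halfwidth_mm = 20) {
  r <- .bin_centers(length(profile), bin_size_mm)
  out <- .profile_split(profile, r, halfwidth_mm)
  if (out["trues"] < 0) {
    out <- c(trues = 0, background = sum(profile))
    attr(out, "clamped") <- TRUE
  }
  out
}

# iterate over the slices of a frame: either an explicit 3-D array
# (bins x angles x slices) in `slices`, or a single expectation sinogram in
# `sino` shared by `n_slices` identical slices.
.frame_slice_totals <- function(frame, bin_size_mm, radius_mm = 120,
                                halfwidth_mm = 20) {
  if (!is.null(frame$slices)) {
    ns <- dim(frame$slices)[3]
    per_slice <- vapply(seq_len(ns), function(s) {
      prof <- align_and_collapse(frame$slices[, , s])
      prof <- mask_beyond_12cm(prof, bin_size_mm, radius_mm)
      split_trues_background(prof, bin_size_mm, halfwidth_mm)
    }, numeric(2))
  } else {
    one <- split_trues_background(
      mask_beyond_12cm(align_and_collapse(frame$sino), bin_size_mm, radius_mm),
      bin_size_mm, halfwidth_mm)
    per_slice <- matrix(one, nrow = 2, ncol = frame$n_slices)
    rownames(per_slice) <- names(one)
  }
  per_slice # 2 x n_slices: trues, background
}

#' Scatter-fraction and count-rate curves from a sinogram acquisition
#'
#' Runs the NU2 single-slice analysis on every frame and slice: align each
#' projection's peak to the centre, mask beyond 12 cm, estimate the scatter +
#' randoms pedestal under the +/-2 cm window by linear interpolation, and
#' accumulate trues and background counts. Randoms come from the delayed
#' channel when the acquisition provides one, or from residual subtraction
#' using the low-activity scatter fraction otherwise. The scatter fraction is
#' reported as the average of `S/(S+T)` over the low-activity frames where
#' randoms are negligible (`R < low_activity_frac * T`), and
#' `NECR = T^2/(T+S+R)` per frame.
#'
#' @param acq a `countrate_acquisition` from [make_countrate_series()] or
#'   [read_countrate()].
#' @param randoms_source `"delayed-provided"` (default when the acquisition
#'   carries delayed counts) or `"model-subtraction"`.
#' @param necr_form `"1R"` for `T^2/(T+S+R)` (default) or `"2R"` for the
#'   online-subtraction variant `T^2/(T+S+2R)`.
#' @param sf_convention `"s-over-s-plus-t"` (default) or `"s-over-total"`
#'   for `S/(S+T+R)` on the qualifying frames.
#' @param low_activity_frac randoms-to-trues ratio below which a frame
#'   qualifies as a low-activity (negligible dead time / randoms) frame.
#' @param volume_mL activity-concentration denominator; defaults to the
#'   acquisition's phantom volume.
#' @return object of class `countrate_curves`: `frames` data frame
#'   (`start_s`, `duration_s`, `activity_MBq`, `activity_conc_kBq_cc`,
#'   `T_kcps`, `S_kcps`, `R_kcps`, `SF_pct`, `NECR_kcps`, `qualifying`),
#'   `summary` list with `SF_reported_pct` and (after [find_necr_peak()])
#'   the peak, plus `slice_trues` (frames x slices) and the calibration
#'   carried over for [randoms_accuracy()].
#' @export
compute_curves <- function(acq,
                           randoms_source = c("delayed-provided",
                                              "model-subtraction"),
                           necr_form = c("1R", "2R"),
                           sf_convention = c("s-over-s-plus-t", "s-over-total"),
                           low_activity_frac = 0.01,
                           volume_mL = NULL) {
  randoms_source <- match.arg(randoms_source)
  necr_form <- match.arg(necr_form)
  sf_convention <- match.arg(sf_convention)
  cal <- acq$calibration
  if (is.null(volume_mL)) volume_mL <- acq$phantom_volume_mL
  nf <- length(acq$frames)
  if (nf < 3L) stop("at least 3 frames are required")
  bin <- cal$bin_size_mm

  start <- vapply(acq$frames, `[[`, numeric(1), "start_s")
  dur <- vapply(acq$frames, `[[`, numeric(1), "duration_s")
  t_mid <- start + dur / 2
  a <- cal$A0_MBq * decay_factor(t_mid - cal$t0_s, cal$half_life_s)

  slice_trues <- NULL
  tot <- vapply(seq_len(nf), function(i) {
    ps <- .frame_slice_totals(acq$frames[[i]], bin)
    slice_trues <<- rbind(slice_trues, ps[1, ])
    rowSums(ps)
  }, numeric(2))
  T_rate <- tot[1, ] / dur
  bg_rate <- tot[2, ] / dur

  if (randoms_source == "delayed-provided" && !is.null(cal$delayed_counts)) {
    R_rate <- cal$delayed_counts / dur
  } else {
    if (randoms_source == "delayed-provided")
      warning("no delayed channel in the acquisition; ",
              "falling back to model-subtraction randoms")
    # low-activity scatter-to-trues ratio from the 3 lowest-activity frames,
    # where randoms are negligible, then R = bg - T * s/(1-s)
    lowest <- order(a)[1:3]
    s0 <- mean(bg_rate[lowest] / (bg_rate[lowest] + T_rate[lowest]))
    R_rate <- pmax(bg_rate - T_rate * s0 / (1 - s0), 0)
  }
  S_rate <- pmax(bg_rate - R_rate, 0)

  qual <- R_rate < low_activity_frac * T_rate & T_rate > 0
  if (!any(qual))
    stop("no qualifying low-activity frames (randoms < ",
         100 * low_activity_frac, "% of trues); extend the decay series")
  if (sum(qual) < 3L)
    warning("only ", sum(qual), " qualifying low-activity frame(s); ",
            "the scatter-fraction average is poorly supported")

  sf_frame <- if (sf_convention == "s-over-s-plus-t") {
    S_rate / (S_rate + T_rate)
  } else {
    S_rate / (S_rate + T_rate + R_rate)
  }
  denom <- T_rate + S_rate + switch(necr_form, "1R" = R_rate, "2R" = 2 * R_rate)
  necr <- ifelse(denom > 0, T_rate^2 / denom, 0)

  frames <- data.frame(
    frame = seq_len(nf), start_s = start, duration_s = dur,
    activity_MBq = a,
    activity_conc_kBq_cc = a * 1000 / volume_mL,
    T_kcps = T_rate / 1000, S_kcps = S_rate / 1000, R_kcps = R_rate / 1000,
    SF_pct = 100 * sf_frame, NECR_kcps = necr / 1000,
    qualifying = qual
  )
  sf_reported <- 100 * mean(sf_frame[qual])
  structure(list(
    frames = frames,
    summary = list(SF_reported_pct = sf_reported,
                   SF_at_peak_pct = NA_real_,
                   NECR_peak_kcps = NA_real_,
                   a_at_peak_kBq_cc = NA_real_),
    slice_trues = slice_trues,
    calibration = cal,
    volume_mL = volume_mL
  ), class = "countrate_curves")
}

#' Refine the NECR peak from computed curves
#'
#' Fits a parabola through the maximum-NECR frame and its two neighbours in
#' (activity concentration, NECR) space and returns the vertex. Falls back
#' to the maximum frame when the parabola is degenerate (non-negative
#' curvature) or its vertex falls outside the neighbour interval.
#'
#' @param curves a [compute_curves()] result.
#' @return list with `NECR_peak_kcps`, `a_at_peak_kBq_cc`, `frame` (index of
#'   the maximum sampled frame), and `refined` (logical).
#' @export
find_necr_peak <- function(curves) {
  fr <- curves$frames
  if (nrow(fr) < 5L) stop("at least 5 frames are required to locate a peak")
  o <- order(fr$activity_conc_kBq_cc)
  x <- fr$activity_conc_kBq_cc[o]
  y <- fr$NECR_kcps[o]
  m <- which.max(y)
  if (m == 1L || m == length(y))
    stop("no-peak error: NECR is monotone over the sampled activity range; ",
         "acquire frames spanning both sides of the peak")
  xs <- x[(m - 1):(m + 1)]; ys <- y[(m - 1):(m + 1)]
  co <- tryCatch(solve(cbind(1, xs, xs^2), ys), error = function(e) NULL)
  refined <- FALSE
  xv <- x[m]; yv <- y[m]
  if (!is.null(co) && is.finite(co[3]) && co[3] < 0) {
    cand_x <- -co[2] / (2 * co[3])
    if (cand_x >= xs[1] && cand_x <= xs[3]) {
      xv <- cand_x
      yv <- co[1] + co[2] * cand_x + co[3] * cand_x^2
      refined <- TRUE
    }
  }
  list(NECR_peak_kcps = unname(yv), a_at_peak_kBq_cc = unname(xv),
       frame = fr$frame[o][m], refined = refined)
}

#' Count-loss and randoms-correction accuracy
#'
#' Applies the acquisition's count-loss (dead-time) correction to the
#' measured trues rates, extrapolates the specific trues rate (cps/MBq)
#' averaged over the qualifying low-activity frames to all activities, and
#' reports the percent deviation of each frame's corrected rate from that
#' extrapolation. The summary is the maximum absolute deviation over frames
#' with activity concentration below the NECR peak.
#'
#' @param curves a [compute_curves()] result.
#' @param per_slice also report per-slice percent errors (matrix frames x
#'   slices) computed from the per-slice trues.
#' @return object of class `accuracy_report`: `frames` data frame (`frame`,
#'   `activity_conc_kBq_cc`, `r_extrapolated_cps`, `r_measured_cps`,
#'   `pct_error`, `below_peak`), `max_abs_pct_error_below_peak`, and
#'   optionally `slice_pct_error`.
#' @export
randoms_accuracy <- function(curves, per_slice = FALSE) {
  fr <- curves$frames
  lam <- curves$calibration$deadtime_lambda_per_MBq
  if (is.null(lam)) {
    warning("acquisition carries no dead-time correction constant; ",
            "treating measured trues as already corrected")
    lam <- 0
  }
  a <- fr$activity_MBq
  corr <- exp(lam * a)
  r_corr <- fr$T_kcps * 1000 * corr          # corrected trues, cps
  spec <- r_corr / a                          # cps/MBq
  qual <- fr$qualifying
  if (!any(qual)) stop("no qualifying low-activity frames for extrapolation")
  r0 <- mean(spec[qual])
  r_extr <- r0 * a
  pct <- 100 * (r_corr - r_extr) / r_extr

  below <- rep(TRUE, nrow(fr))
  pk <- tryCatch(find_necr_peak(curves), error = function(e) NULL)
  if (is.null(pk)) {
    warning("NECR peak unknown (monotone curve); ",
            "accuracy summary computed over all frames")
  } else {
    below <- fr$activity_conc_kBq_cc < pk$a_at_peak_kBq_cc
  }
  out <- list(
    frames = data.frame(frame = fr$frame,
                        activity_conc_kBq_cc = fr$activity_conc_kBq_cc,
                        r_extrapolated_cps = r_extr,
                        r_measured_cps = r_corr,
                        pct_error = pct,
                        below_peak = below),
    max_abs_pct_error_below_peak = max(abs(pct[below]))
  )
  if (per_slice && !is.null(curves$slice_trues)) {
    ns <- ncol(curves$slice_trues)
    sl_rate <- curves$slice_trues / fr$duration_s * corr # cps per slice
    sl_spec <- sl_rate / a
    sl_r0 <- colMeans(sl_spec[qual, , drop = FALSE])
    out$slice_pct_error <- 100 * sweep(sweep(sl_spec, 2, sl_r0, "/"), 2, 1, "-")
  }
  structure(out, class = "accuracy_report")
}

#' @export
print.countrate_curves <- function(x, digits = 3, ...) {
  cat("NU2 scatter-fraction / count-rate curves\n")
  cat(sprintf("  SF (low-activity average): %.4g %%\n",
              x$summary$SF_reported_pct))
  if (is.finite(x$summary$NECR_peak_kcps %||% NA_real_))
    cat(sprintf("  NECR peak: %.4g kcps at %.4g kBq/cc\n",
                x$summary$NECR_peak_kcps, x$summary$a_at_peak_kBq_cc))
  df <- x$frames
  df[sapply(df, is.numeric)] <- lapply(df[sapply(df, is.numeric)], signif,
                                       digits)
  print(utils::head(df, 8), row.names = FALSE)
  if (nrow(x$frames) > 8) cat("  ... ", nrow(x$frames), "frames total\n")
  invisible(x)
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Count-loss / randoms-correction accuracy\n")
  cat(sprintf("  max |error| below NECR peak: %.3g %%\n",
              x$max_abs_pct_error_below_peak))
  invisible(x)
}
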