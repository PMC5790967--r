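#' Simulate the five-sleeve sensitivity acquisition
#'
#' Generates the per-sleeve count records of the NU2 sensitivity test: a low
#' activity line source measured five times, each time inside one more
#' aluminium sleeve. The detected count rate for configuration `j` is
#' \deqn{rate_j = S_0 \, A(t_j) \, e^{-2 \mu_{alu} X_j},}
#' where `X_j = j * 1.25` mm is the accumulated wall thickness (the factor 2
#' models the annihilation photon pair traversing both walls; the analysis
#' inverts the same log-linear model), and `A(t)` is the decayed activity at
#' the frame mid-time. Activity is assumed low enough that dead time is
#' negligible, as the protocol requires.
#'
#' Per-slice counts follow a triangular axial profile (the slice sensitivity
#' of a 3-D acquisition of a line source spanning the axial field of view).
#'
#' @param S0_cps_kBq attenuation-free system sensitivity, cps/kBq — the
#'   ground truth the analysis should recover.
#' @param mu_alu_per_mm effective attenuation coefficient of aluminium, 1/mm.
#' @param activity_kBq source activity at the reference time (t = 0).
#' @param frame_duration_s duration of each of the five measurements.
#' @param start_times_s start time of each measurement, seconds from the
#'   reference time (length 5).
#' @param n_slices number of axial slices.
#' @param noise `"none"` for expectation values, `"poisson"` for counting
#'   noise.
#' @param seed RNG seed used when `noise = "poisson"`.
#' @param half_life_s isotope half-life, seconds.
#' @param position position tag, `"center"` or `"10 cm offset"`.
#' @param geometry a [phantom_geometry()] (supplies the wall thickness).
#' @return object of class `sleeve_acquisition`: `sleeves` data frame
#'   (`sleeve`, `X_mm`, `counts`, `start_s`, `duration_s`), `slice_counts`
#'   matrix (slices x sleeves), `source` (activity, reference time,
#'   half-life), `position`, `low_count_slices` (slices of sleeve 1 with
#'   fewer than 10,000 counts), and a `ground_truth` record.
#' @examples
#' acq <- make_sleeve_series(22.2, 0.05, 5000, 60, seq(0, 1200, by = 300))
#' acq$sleeves$counts / acq$sleeves$duration_s
#' @export
make_sleeve_series <- function(S0_cps_kBq, mu_alu_per_mm, activity_kBq,
                               frame_duration_s, start_times_s,
                               n_slices = 45,
                               noise = c("none", "poisson"),
                               seed = 0,
                               half_life_s = F18_HALF_LIFE_S,
                               position = "center",
                               geometry = phantom_geometry()) {
  noise <- match.arg(noise)
  if (!is.finite(activity_kBq) || activity_kBq <= 0)
    stop("activity_kBq must be positive")
  if (S0_cps_kBq <= 0) stop("S0_cps_kBq must be positive")
  if (mu_alu_per_mm < 0) stop("mu_alu_per_mm must be nonnegative")
  if (length(start_times_s) != 5L)
    stop("the sensitivity test has exactly 5 sleeve configurations")
  if (frame_duration_s <= 0) stop("frame_duration_s must be positive")
  wall <- geometry$sleeve_wall_thickness_mm
  j <- 1:5
  X <- j * wall
  t_mid <- start_times_s + frame_duration_s / 2
  a_mid <- activity_kBq * decay_factor(t_mid, half_life_s)
  rates <- S0_cps_kBq * a_mid * exp(-2 * mu_alu_per_mm * X)
  counts <- rates * frame_duration_s
  # triangular axial slice profile, peaked at the axial centre
  centre <- (n_slices + 1) / 2
  w <- pmax(1 - abs(seq_len(n_slices) - centre) / centre, 1e-6)
  w <- w / sum(w)
  slice_counts <- outer(w, counts)
  if (noise == "poisson") {
    set.seed(seed)
    slice_counts[] <- stats::rpois(length(slice_counts), slice_counts)
    counts <- colSums(slice_counts)
  }
  structure(list(
    sleeves = data.frame(sleeve = j, X_mm = X, counts = counts,
                         start_s = start_times_s,
                         duration_s = frame_duration_s),
    slice_counts = slice_counts,
    source = list(activity_kBq = activity_kBq, ref_time_s = 0,
                  half_life_s = half_life_s),
    position = position,
    low_count_slices = which(slice_counts[, 1] < 10000),
    ground_truth = list(S0_true_cps_kBq = S0_cps_kBq,
                        mu_alu_per_mm = mu_alu_per_mm,
                        slope_true_per_mm = -2 * mu_alu_per_mm)
  ), class = "sleeve_acquisition")
}
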