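#' IEC body-phantom geometry for the image-quality test
#'
#' Positions of the six fillable spheres (10-37 mm inner diameter, on a
#' 114.4 mm diameter ring in the central transverse plane), the central lung
#' insert, and the twelve background ROI positions near the phantom edge.
#' The phantom body is modelled as a circular section of 250 mm diameter
#' (the torso's long dimension), which keeps every background ROI at least
#' 15 mm from the spheres and the edge.
#'
#' @param sphere_diameters_mm six inner diameters, strictly increasing; the
#'   four smallest are hot, the two largest cold.
#' @param sphere_ring_radius_mm radius of the sphere-centre ring.
#' @param lung_diameter_mm lung-insert diameter.
#' @param lung_roi_diameter_mm diameter of the lung ROI.
#' @param body_radius_mm phantom section radius.
#' @param bg_ring_radius_mm radius of the background ROI ring.
#' @param bg_angles_deg twelve in-plane background ROI angles.
#' @param bg_slice_offsets_mm axial offsets of the background ROI slices
#'   (replicated at the central slice and +/-10, +/-20 mm).
#' @param nominal_ratio filled hot-sphere to background activity ratio.
#' @return object of class `iq_geometry`.
#' @export
iq_geometry <- function(sphere_diameters_mm = c(10, 13, 17, 22, 28, 37),
                        sphere_ring_radius_mm = 57.2,
                        lung_diameter_mm = 50,
                        lung_roi_diameter_mm = 30,
                        body_radius_mm = 125,
                        bg_ring_radius_mm = 90,
                        bg_angles_deg = seq(15, 345, by = 30),
                        bg_slice_offsets_mm = c(-20, -10, 0, 10, 20),
                        nominal_ratio = 8) {
  stopifnot(length(sphere_diameters_mm) == 6L,
            all(diff(sphere_diameters_mm) > 0),
            length(bg_angles_deg) == 12L,
            nominal_ratio > 1)
  ang <- seq(0, 300, by = 60) * pi / 180
  centers <- cbind(x = sphere_ring_radius_mm * cos(ang),
                   y = sphere_ring_radius_mm * sin(ang))
  bga <- bg_angles_deg * pi / 180
  bg_centers <- cbind(x = bg_ring_radius_mm * cos(bga),
                      y = bg_ring_radius_mm * sin(bga))
  # layout invariants: non-overlapping spheres, background ROIs >= 15 mm
  # from every sphere surface and from the phantom edge
  rs <- sphere_diameters_mm / 2
  dd <- as.matrix(stats::dist(centers))
  sep <- dd - outer(rs, rs, "+")
  if (any(sep[upper.tri(sep)] <= 0)) stop("spheres overlap")
  for (k in seq_len(6)) {
    d_to_sph <- sqrt((bg_centers[, 1] - rep(centers[, 1], each = 12))^2 +
                     (bg_centers[, 2] - rep(centers[, 2], each = 12))^2)
    if (any(d_to_sph - rep(rs, each = 12) < 15))
      stop("a background ROI centre is closer than 15 mm to a sphere")
    if (any(bg_ring_radius_mm + rs[k] > body_radius_mm - 15))
      stop("background ROIs of size ", sphere_diameters_mm[k],
           " mm are closer than 15 mm to the phantom edge")
  }
  structure(list(
    sphere_diameters_mm = sphere_diameters_mm,
    sphere_centers_mm = centers,
    lung_center_mm = c(0, 0),
    lung_diameter_mm = lung_diameter_mm,
    lung_roi_diameter_mm = lung_roi_diameter_mm,
    body_radius_mm = body_radius_mm,
    bg_centers_mm = bg_centers,
    bg_slice_offsets_mm = bg_slice_offsets_mm,
    nominal_ratio = nominal_ratio
  ), class = "iq_geometry")
}

#' Measured sphere-to-background ratio for a target hot contrast
#'
#' Inverts the hot-contrast formula: a hot sphere measured at
#' `C_H/C_B = 1 + Q_H (ratio - 1)/100` reports percent contrast `Q_H` at
#' nominal fill ratio `ratio`.
#'
#' @param contrast_pct target percent contrast.
#' @param nominal_ratio filled activity ratio (8 for this protocol).
#' @return the measured ratio `C_H/C_B`.
#' @examples
#' ratio_for_hot_contrast(85) # 6.95
#' @export
ratio_for_hot_contrast <- function(contrast_pct, nominal_ratio = 8) {
  1 + contrast_pct * (nominal_ratio - 1) / 100
}

#' Measured ratio for a target cold contrast
#'
#' @param contrast_pct target percent cold contrast.
#' @return the measured ratio `C_C/C_B = 1 - Q_C/100`.
#' @export
ratio_for_cold_contrast <- function(contrast_pct) {
  1 - contrast_pct / 100
}

#' Simulate a reconstructed IEC body-phantom volume
#'
#' Paints an image-domain emulation of the IQ-phantom reconstruction: a
#' uniform background inside the phantom body, six spheres at their measured
#' sphere-to-background ratios, and the lung insert at `lung_fraction` of
#' the background. Voxel membership is by voxel-centre-inside-shape, the
#' same rule the ROI analysis uses, so in noise-free mode the ROI means
#' reproduce the requested ratios exactly. Optional Gaussian voxel noise
#' (truncated at zero) with standard deviation `noise_cv_voxel *
#' background_level` is added inside the body; the background variability
#' for ROIs of `n` voxels is then approximately
#' `100 * noise_cv_voxel / sqrt(n)`.
#'
#' @param background_level background activity level (arbitrary units).
#' @param sphere_measured_ratios per-sphere measured-to-background ratios,
#'   ordered as `geometry$sphere_diameters_mm`; the four smallest must be
#'   hot (> 1 sensible) and the two largest cold (< 1).
#' @param lung_fraction lung-insert level as a fraction of background.
#' @param voxel_size_mm isotropic voxel size; must be at most 1/3 of the
#'   smallest sphere diameter.
#' @param noise_cv_voxel per-voxel coefficient of variation of the added
#'   Gaussian noise (0 = noise-free).
#' @param seed RNG seed used when noise is added.
#' @param geometry an [iq_geometry()].
#' @return object of class `iq_volume`: `voxels` (3-D array), `voxel_size`,
#'   `geometry`, and a `ground_truth` record with the implied contrasts and
#'   lung residual.
#' @examples
#' vol <- make_iq_image(1, c(5.48, 6.04, 6.46, 6.95, 0.25, 0.25), 0.012)
#' iq_report(vol)
#' @export
make_iq_image <- function(background_level = 1,
                          sphere_measured_ratios,
                          lung_fraction,
                          voxel_size_mm = 2,
                          noise_cv_voxel = 0,
                          seed = 0,
                          geometry = iq_geometry()) {
  stopifnot(length(sphere_measured_ratios) == 6L)
  if (any(sphere_measured_ratios <= 0))
    stop("sphere measured ratios must be positive")
  if (lung_fraction < 0) stop("lung_fraction must be nonnegative")
  if (background_level <= 0) stop("background_level must be positive")
  if (voxel_size_mm > min(geometry$sphere_diameters_mm) / 3)
    stop("voxel size must be at most 1/3 of the smallest sphere diameter")
  if (any(sphere_measured_ratios[5:6] >= 1))
    warning("the two largest spheres are cold in this protocol; ",
            "ratios >= 1 for them are unusual")

  half_xy <- geometry$body_radius_mm + 2 * voxel_size_mm
  half_z <- max(abs(geometry$bg_slice_offsets_mm)) +
    max(geometry$sphere_diameters_mm) / 2 + 2 * voxel_size_mm
  nx <- 2L * ceiling(half_xy / voxel_size_mm) + 1L
  nz <- 2L * ceiling(half_z / voxel_size_mm) + 1L
  cx <- (seq_len(nx) - (nx + 1) / 2) * voxel_size_mm
  cz <- (seq_len(nz) - (nz + 1) / 2) * voxel_size_mm

  vox <- array(0, dim = c(nx, nx, nz))
  rho2 <- outer(cx^2, cx^2, "+")
  body <- rho2 <= geometry$body_radius_mm^2
  lung <- rho2 <= (geometry$lung_diameter_mm / 2)^2
  plane <- ifelse(body, background_level, 0)
  plane[lung] <- lung_fraction * background_level
  for (k in seq_len(nz)) vox[, , k] <- plane
  kz0 <- which.min(abs(cz)) # central slice (z = 0)
  for (s in seq_len(6)) {
    ctr <- geometry$sphere_centers_mm[s, ]
    rad <- geometry$sphere_diameters_mm[s] / 2
    for (k in seq_len(nz)) {
      dz2 <- cz[k]^2
      if (dz2 > rad^2) next
      d2 <- outer((cx - ctr[1])^2, (cx - ctr[2])^2, "+") + dz2
      sel <- d2 <= rad^2
      sl <- vox[, , k]
      sl[sel] <- sphere_measured_ratios[s] * background_level
      vox[, , k] <- sl
    }
  }
  if (noise_cv_voxel > 0) {
    set.seed(seed)
    noise <- array(stats::rnorm(length(vox), 0,
                                noise_cv_voxel * background_level),
                   dim = dim(vox))
    inb <- array(rep(body, nz), dim = dim(vox))
    vox[inb] <- pmax(vox[inb] + noise[inb], 0)
  }
  gt <- list(
    contrast_true_pct = c(
      100 * (sphere_measured_ratios[1:4] - 1) / (geometry$nominal_ratio - 1),
      100 * (1 - sphere_measured_ratios[5:6])),
    lung_residual_true_pct = 100 * lung_fraction,
    noise_cv_voxel = noise_cv_voxel
  )
  structure(list(voxels = vox,
                 voxel_size = rep(voxel_size_mm, 3),
                 central_slice = kz0,
                 geometry = geometry,
                 ground_truth = gt),
            class = "iq_volume")
}
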