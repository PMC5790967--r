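#' Place the image-quality ROIs on a volume
#'
#' For each sphere size: a circular ROI of the sphere's inner diameter
#' centred on the sphere in the central transverse slice, plus the twelve
#' background ROIs of the same diameter replicated on the central slice and
#' the slices at +/-10 and +/-20 mm (60 background samples per size). A
#' circular lung ROI sits on the lung insert in the central slice. Voxel
#' membership is by voxel-centre-inside-circle.
#'
#' @param volume an `iq_volume` (see [make_iq_image()]) or compatible list
#'   with `voxels`, `voxel_size`, `central_slice`.
#' @param geometry an [iq_geometry()]; defaults to the volume's own.
#' @return object of class `roi_set`: per sphere size, the sphere ROI voxel
#'   values and a 60-element list of background ROI values; plus the lung
#'   ROI values.
#' @export
place_rois <- function(volume, geometry = volume$geometry) {
  vox <- volume$voxels
  d <- dim(vox)
  vs <- volume$voxel_size
  if (vs[1] > min(geometry$sphere_diameters_mm) / 3)
    stop("voxel size must be at most 1/3 of the smallest sphere diameter")
  cx <- (seq_len(d[1]) - (d[1] + 1) / 2) * vs[1]
  cy <- (seq_len(d[2]) - (d[2] + 1) / 2) * vs[2]
  cz <- (seq_len(d[3]) - (d[3] + 1) / 2) * vs[3]
  kz0 <- volume$central_slice %||% which.min(abs(cz))

  circle_vals <- function(center_xy, diameter, kz, roi_name) {
    rad <- diameter / 2
    if (center_xy[1] - rad < min(cx) || center_xy[1] + rad > max(cx) ||
        center_xy[2] - rad < min(cy) || center_xy[2] + rad > max(cy) ||
        kz < 1 || kz > d[3])
      stop("ROI '", roi_name, "' is clipped by the volume edge")
    sel <- outer((cx - center_xy[1])^2, (cy - center_xy[2])^2, "+") <= rad^2
    vox[, , kz][sel]
  }
  slice_idx <- vapply(geometry$bg_slice_offsets_mm,
                      function(off) which.min(abs(cz - off)), integer(1))
  spheres <- lapply(seq_len(6), function(s) {
    dia <- geometry$sphere_diameters_mm[s]
    sph <- circle_vals(geometry$sphere_centers_mm[s, ], dia, kz0,
                       paste0("sphere ", dia, " mm"))
    bg <- list()
    for (kz in slice_idx) {
      for (p in seq_len(nrow(geometry$bg_centers_mm))) {
        bg[[length(bg) + 1L]] <- circle_vals(
          geometry$bg_centers_mm[p, ], dia, kz,
          paste0("background ", dia, " mm, position ", p))
      }
    }
    list(diameter_mm = dia, sphere_values = sph, background_values = bg)
  })
  lung <- circle_vals(geometry$lung_center_mm, geometry$lung_roi_diameter_mm,
                      kz0, "lung insert")
  structure(list(spheres = spheres, lung_values = lung,
                 geometry = geometry), class = "roi_set")
}

#' Percent contrast of a hot sphere
#'
#' `Q_H = 100 * ((C_H/C_B) - 1) / (ratio - 1)`, normalising the measured
#' sphere-to-background ratio by the filled activity ratio.
#'
#' @param C_H hot-sphere ROI mean.
#' @param C_B matched background ROI mean.
#' @param ratio filled hot-to-background activity ratio (> 1).
#' @return percent contrast.
#' @examples
#' hot_contrast(6.95, 1, 8) # 85
#' @export
hot_contrast <- function(C_H, C_B, ratio = 8) {
  if (any(C_B <= 0)) stop("background mean must be positive")
  if (ratio <= 1) stop("activity ratio must exceed 1 for a hot sphere")
  100 * ((C_H / C_B) - 1) / (ratio - 1)
}

#' Percent contrast of a cold sphere
#'
#' `Q_C = 100 * (1 - C_C/C_B)`.
#'
#' @param C_C cold-sphere ROI mean (nonnegative).
#' @param C_B matched background ROI mean.
#' @return percent contrast.
#' @export
cold_contrast <- function(C_C, C_B) {
  if (any(C_B <= 0)) stop("background mean must be positive")
  if (any(C_C < 0)) stop("cold-sphere mean must be nonnegative")
  100 * (1 - C_C / C_B)
}

#' Background variability
#'
#' Percent coefficient of variation of the background ROI means for one
#' sphere size: `N = 100 * SD(means) / mean(means)` with the sample (n-1)
#' standard deviation.
#'
#' @param background_means vector of background ROI means (length >= 2).
#' @return percent variability.
#' @examples
#' background_variability(c(90, 100, 110)) # 10
#' @export
background_variability <- function(background_means) {
  if (length(background_means) < 2L)
    stop("at least 2 background ROIs are required")
  100 * stats::sd(background_means) / mean(background_means)
}

#' Residual lung-insert activity
#'
#' `100 * C_lung / C_B`: the lung ROI mean as a percentage of background —
#' a probe of attenuation and scatter correction accuracy.
#'
#' @param C_lung lung ROI mean.
#' @param C_B background mean.
#' @return percent residual.
#' @export
lung_residual <- function(C_lung, C_B) {
  if (any(C_B <= 0)) stop("background mean must be positive")
  100 * C_lung / C_B
}

#' Image-quality report for an IEC body-phantom volume
#'
#' Composes the four IQ metrics from the ROI set: percent contrast for the
#' four hot and two cold spheres (each against the mean of its own-size
#' background ROIs), background variability per sphere size, the lung
#' residual, and the mean contrast across the hot spheres.
#'
#' @param volume an `iq_volume`.
#' @param geometry an [iq_geometry()]; defaults to the volume's own.
#' @param ratio filled hot-to-background activity ratio.
#' @return object of class `iq_report`: `spheres` data frame
#'   (`diameter_mm`, `type`, `roi_mean`, `background_mean`, `contrast_pct`,
#'   `background_variability_pct`), `lung_residual_pct`,
#'   `mean_hot_contrast_pct`.
#' @export
iq_report <- function(volume, geometry = volume$geometry,
                      ratio = geometry$nominal_ratio) {
  rois <- place_rois(volume, geometry)
  n_sph <- length(rois$spheres)
  rows <- lapply(seq_len(n_sph), function(s) {
    sp <- rois$spheres[[s]]
    bg_means <- vapply(sp$background_values, mean, numeric(1))
    C_B <- mean(bg_means)
    C_roi <- mean(sp$sphere_values)
    hot <- s <= 4
    data.frame(
      diameter_mm = sp$diameter_mm,
      type = if (hot) "hot" else "cold",
      roi_mean = C_roi,
      background_mean = C_B,
      contrast_pct = if (hot) hot_contrast(C_roi, C_B, ratio)
                     else cold_contrast(C_roi, C_B),
      background_variability_pct = background_variability(bg_means),
      stringsAsFactors = FALSE
    )
  })
  spheres <- do.call(rbind, rows)
  C_B_all <- mean(spheres$background_mean)
  structure(list(
    spheres = spheres,
    lung_residual_pct = lung_residual(mean(rois$lung_values), C_B_all),
    mean_hot_contrast_pct = mean(spheres$contrast_pct[spheres$type == "hot"])
  ), class = "iq_report")
}

#' @export
print.iq_report <- function(x, digits = 3, ...) {
  cat("IEC body-phantom image-quality report\n")
  df <- x$spheres
  df[sapply(df, is.numeric)] <- lapply(df[sapply(df, is.numeric)], round,
                                       digits)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("  mean hot contrast: %.4g %%\n", x$mean_hot_contrast_pct))
  cat(sprintf("  lung residual    : %.4g %%\n", x$lung_residual_pct))
  invisible(x)
}
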