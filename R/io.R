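#' Write / read a point-source volume
#'
#' Volumes are stored either as NIfTI-1 (`format = "nifti"`, via RNifti,
#' with the voxel size in the header) or as raw little-endian float32
#' (`format = "raw"`). Either way a JSON sidecar (`<path>.json`) carries the
#' shape, voxel size, nominal position, label and ground truth.
#'
#' @param volume a `psf_volume` (or `iq_volume`).
#' @param path output path without extension.
#' @param format `"nifti"` or `"raw"`.
#' @return `write_volume` returns the main file path invisibly;
#'   `read_volume` returns the reconstructed volume object.
#' @export
write_volume <- function(volume, path, format = c("nifti", "raw")) {
  format <- match.arg(format)
  meta <- list(
    format = format,
    shape = dim(volume$voxels),
    voxel_size_mm = volume$voxel_size,
    nominal_position_mm = volume$nominal_position,
    label = volume$label,
    central_slice = volume$central_slice,
    class = class(volume)[1],
    ground_truth = volume$ground_truth
  )
  if (format == "nifti") {
    file <- paste0(path, ".nii")
    img <- RNifti::asNifti(volume$voxels, pixdim = volume$voxel_size)
    RNifti::writeNifti(img, file)
  } else {
    file <- paste0(path, ".f32")
    con <- file(file, "wb")
    on.exit(close(con))
    writeBin(as.numeric(volume$voxels), con, size = 4, endian = "little")
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (identical(meta$format, "nifti")) {
    vox <- array(as.numeric(RNifti::readNifti(paste0(path, ".nii"))),
                 dim = meta$shape)
  } else {
    con <- file(paste0(path, ".f32"), "rb")
    on.exit(close(con))
    vox <- array(readBin(con, "numeric", prod(meta$shape), size = 4,
                         endian = "little"),
                 dim = meta$shape)
  }
  structure(list(voxels = vox,
                 voxel_size = meta$voxel_size_mm,
                 nominal_position = meta$nominal_position_mm,
                 label = meta$label,
                 central_slice = meta$central_slice,
                 geometry = NULL,
                 ground_truth = meta$ground_truth),
            class = meta$class %||% "psf_volume")
}

#' Write / read a count-rate sinogram series
#'
#' The series container is a directory holding `header.json` (frame times,
#' sinogram shape, calibration block with `A0_MBq`, `t0_s`, `half_life_s`,
#' `bin_size_mm`, dead-time constant and delayed counts, phantom volume and
#' ground truth) and one raw little-endian float64 file per frame
#' (`frame_<i>.f64`, radial bins fastest, then angles, then slices).
#'
#' @param acq a `countrate_acquisition`.
#' @param dir output directory (created if needed).
#' @return `write_countrate` returns `dir` invisibly; `read_countrate`
#'   returns the acquisition.
#' @export
write_countrate <- function(acq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames_meta <- lapply(seq_along(acq$frames), function(i) {
    f <- acq$frames[[i]]
    if (!is.null(f$slices)) {
      arr <- f$slices
      shape <- dim(arr)
      replicated <- FALSE
    } else {
      arr <- f$sino
      shape <- c(dim(arr), f$n_slices)
      replicated <- TRUE
    }
    con <- file(file.path(dir, sprintf("frame_%03d.f64", i)), "wb")
    writeBin(as.numeric(arr), con, size = 8, endian = "little")
    close(con)
    list(start_s = f$start_s, duration_s = f$duration_s,
         shape = shape, replicated_slices = replicated)
  })
  header <- list(container = "petperf-countrate-v1",
                 frames = frames_meta,
                 calibration = acq$calibration,
                 phantom_volume_mL = acq$phantom_volume_mL,
                 ground_truth = acq$ground_truth)
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_countrate
#' @export
read_countrate <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "header.json"),
                                simplifyVector = TRUE)
  nf <- nrow(header$frames)
  frames <- lapply(seq_len(nf), function(i) {
    fm <- header$frames[i, ]
    shape <- unlist(fm$shape)
    con <- file(file.path(dir, sprintf("frame_%03d.f64", i)), "rb")
    on.exit(close(con))
    if (isTRUE(fm$replicated_slices)) {
      sino <- matrix(readBin(con, "numeric", shape[1] * shape[2], size = 8,
                             endian = "little"), nrow = shape[1])
      list(start_s = fm$start_s, duration_s = fm$duration_s,
           sino = sino, n_slices = shape[3])
    } else {
      arr <- array(readBin(con, "numeric", prod(shape), size = 8,
                           endian = "little"), dim = shape)
      list(start_s = fm$start_s, duration_s = fm$duration_s, slices = arr)
    }
  })
  cal <- as.list(header$calibration)
  cal$delayed_counts <- unlist(cal$delayed_counts)
  structure(list(frames = frames,
                 calibration = cal,
                 phantom = phantom_geometry(),
                 phantom_volume_mL = header$phantom_volume_mL,
                 ground_truth = header$ground_truth),
            class = "countrate_acquisition")
}

#' Write / read a sleeve sensitivity acquisition
#'
#' Sleeve records go to CSV (`sleeve`, `X_mm`, `counts`, `start_s`,
#' `duration_s`) with the source block, per-slice counts and ground truth in
#' a JSON sidecar.
#'
#' @param acq a `sleeve_acquisition`.
#' @param path output path without extension.
#' @return `write_sleeves` returns the CSV path invisibly; `read_sleeves`
#'   the acquisition.
#' @export
write_sleeves <- function(acq, path) {
  csv <- paste0(path, ".csv")
  utils::write.csv(acq$sleeves, csv, row.names = FALSE)
  jsonlite::write_json(list(source = acq$source, position = acq$position,
                            slice_counts = acq$slice_counts,
                            ground_truth = acq$ground_truth),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(csv)
}

#' @rdname write_sleeves
#' @export
read_sleeves <- function(path) {
  sleeves <- utils::read.csv(paste0(path, ".csv"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(sleeves = sleeves,
                 slice_counts = meta$slice_counts,
                 source = as.list(meta$source),
                 position = meta$position,
                 ground_truth = meta$ground_truth),
            class = "sleeve_acquisition")
}

#' Write / read a ground-truth sidecar
#'
#' Every generator records the nominal values it was calibrated to in its
#' `ground_truth` field; these helpers serialise that record to JSON so
#' recovery checks can run against saved fixtures.
#'
#' @param ground_truth a ground-truth list (or an object with a
#'   `ground_truth` field).
#' @param path JSON file path.
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` the list.
#' @export
write_ground_truth <- function(ground_truth, path) {
  if (!is.null(ground_truth$ground_truth))
    ground_truth <- ground_truth$ground_truth
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
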