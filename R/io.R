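#' Write an image series as NIfTI with a JSON protocol sidecar
#'
#' The series goes out as a NIfTI-1 volume (4th dimension = acquisition
#' index, voxel dimensions from the geometry) next to a `.json` sidecar
#' holding the protocol fields.
#'
#' @param series an `mpmri_series`.
#' @param prefix path prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>.json`.
#' @return the two paths, invisibly.
#' @export
write_series_nifti <- function(series, prefix) {
  stopifnot(inherits(series, "mpmri_series"))
  d <- dim(series$data)
  arr <- array(series$data, c(d[1], d[2], 1, d[3]))
  g <- series$geometry
  vx <- g$fov_mm / d[1]
  img <- RNifti::asNifti(arr, pixdim = c(vx, vx, g$slice_thickness_mm, 1))
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(img, nii)
  json <- paste0(prefix, ".json")
  proto <- unclass(series$protocol)
  jsonlite::write_json(proto, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(nii, json))
}

#' Read an image series written by [write_series_nifti()]
#'
#' @param prefix the path prefix used at write time.
#' @return an `mpmri_series`.
#' @export
read_series_nifti <- function(prefix) {
  arr <- as.array(RNifti::readNifti(paste0(prefix, ".nii.gz")))
  d <- dim(arr)
  data <- array(arr, c(d[1], d[2], d[length(d)]))
  proto <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  proto$n_acq <- as.integer(proto$n_acq)
  class(proto) <- "mpmri_protocol"
  structure(list(data = data, protocol = proto, geometry = proto$geometry),
            class = "mpmri_series")
}

#' Write an integer label mask as NIfTI
#'
#' @param mask integer matrix (ROI labels or phantom labels).
#' @param path output `.nii.gz` path.
#' @param geometry list with `fov_mm`, `slice_thickness_mm`.
#' @export
write_mask_nifti <- function(mask, path,
                             geometry = list(fov_mm = 21, slice_thickness_mm = 1.25)) {
  vx <- geometry$fov_mm / nrow(mask)
  img <- RNifti::asNifti(array(as.integer(mask), c(dim(mask), 1)),
                         pixdim = c(vx, vx, geometry$slice_thickness_mm))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read the long-format ROI table as CSV
#'
#' @param table ROI table data frame.
#' @param path CSV path.
#' @export
write_roi_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_table
#' @export
read_roi_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a spectrum as a two-column CSV (ppm, intensity)
#'
#' @param spectrum an `mpmri_spectrum`.
#' @param path CSV path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(ppm = spectrum$ppm,
                              intensity = spectrum$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(list(ppm = d$ppm, intensity = d$intensity,
                 metadata = list(), truth = NULL),
            class = "mpmri_spectrum")
}
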