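#' Default per-region ground truth for the digital phantom
#'
#' Signal amplitude (a.u.), T2 (ms), ADC (um^2/s) and MTR (percent) for the
#' brain regions of the phantom. Tissue values sit inside the retention
#' filters (30 < T2 < 80 ms, 0 < ADC < 1200 um^2/s, MTR > 0); the CSF row
#' is deliberately outside all three (long T2, fast diffusion, zero MTR)
#' so that value filtering is exercised downstream.
#'
#' @return data frame with columns region, S0, T2_ms, ADC_um2s, MTR_percent.
#' @export
default_region_truth <- function() {
  data.frame(
    region      = c("other_brain", "csf", "hypothalamus", "hippocampus", "nac", "ila"),
    S0          = c(1000, 1800, 1000, 1000, 1000, 1000),
    T2_ms       = c(48, 150, 45, 50, 55, 60),
    ADC_um2s    = c(720, 2500, 700, 750, 650, 600),
    MTR_percent = c(33, 0, 35, 32, 38, 30),
    stringsAsFactors = FALSE
  )
}

#' Build a digital phantom with known per-region MR parameters
#'
#' Constructs a 2-D labelled slice: a circular brain with a CSF rim,
#' other-brain tissue, and the four template ROIs (hypothalamus,
#' hippocampus, NAc, ILA) embedded at their template positions. Every
#' labelled voxel carries the ground-truth S0/T2/ADC/MTR of its region,
#' which the simulators and fitters consume.
#'
#' @param truth per-region parameter table as in [default_region_truth()];
#'   must cover every region placed in the label image.
#' @param geometry list with `matrix` (image side, voxels), `fov_mm`,
#'   `slice_thickness_mm`.
#' @param template ROI template used to place the four regions.
#' @return object of class `mpmri_phantom`: list with `label` (integer
#'   matrix), `region_codes`, `truth`, `geometry`.
#' @examples
#' ph <- make_phantom()
#' table(ph$label)
#' @export
make_phantom <- function(truth = default_region_truth(),
                         geometry = list(matrix = 128L, fov_mm = 21,
                                         slice_thickness_mm = 1.25),
                         template = roi_template()) {
  n <- as.integer(geometry$matrix)
  if (length(n) != 1 || is.na(n) || n <= 0) stop("geometry must give a positive matrix size")
  stopifnot(is.data.frame(truth), "region" %in% names(truth))
  if (any(truth$T2_ms <= 0)) stop("all T2 must be > 0")
  if (any(truth$ADC_um2s < 0)) stop("all ADC must be >= 0")
  if (any(truth$MTR_percent < 0 | truth$MTR_percent >= 100))
    stop("MTR must lie in [0, 100)")

  roi <- make_roi_masks(template, list(matrix = n))
  codes <- attr(roi, "region_codes")

  ctr <- (n + 1) / 2
  r <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  label <- matrix(0L, n, n)
  label[r <= 0.46 * n] <- codes[["csf"]]
  label[r <= 0.41 * n] <- codes[["other_brain"]]
  if (any(roi != 0L & label != codes[["other_brain"]]))
    stop("geometry too small: ROI template extends outside the brain tissue")
  label[roi != 0L] <- roi[roi != 0L]

  placed <- names(codes)[codes %in% unique(as.vector(label))]
  missing <- setdiff(placed, truth$region)
  if (length(missing))
    stop("region(s) missing from truth table: ", paste(missing, collapse = ", "))

  structure(list(label = label, region_codes = codes,
                 truth = truth, geometry = geometry),
            class = "mpmri_phantom")
}

#' @export
print.mpmri_phantom <- function(x, ...) {
  cat("<mpmri_phantom>", nrow(x$label), "x", ncol(x$label), "slice;",
      sum(x$label > 0), "labelled voxels in",
      length(setdiff(unique(as.vector(x$label)), 0L)), "regions\n")
  invisible(x)
}

# per-voxel parameter image from the phantom truth (0 outside the head)
phantom_param_image <- function(phantom, column) {
  vals <- stats::setNames(phantom$truth[[column]], phantom$truth$region)
  img <- matrix(0, nrow(phantom$label), ncol(phantom$label))
  for (reg in names(phantom$region_codes)) {
    code <- phantom$region_codes[[reg]]
    if (any(phantom$label == code)) {
      if (!reg %in% names(vals)) stop("region missing from truth: ", reg)
      img[phantom$label == code] <- vals[[reg]]
    }
  }
  img
}
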