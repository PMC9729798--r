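#' Acquisition protocols
#'
#' Build the default acquisition protocol for one of the four sequence
#' families used in the study: multi-echo T2 mapping, diffusion-weighted
#' imaging (the 9 b-value male protocol or the shorter 3 b-value female
#' protocol), and the magnetization-transfer on/off pair. Defaults follow
#' the published sequence parameters; any field can be overridden.
#'
#' @param kind one of `"t2map"`, `"dwi_male"`, `"dwi_female"`, `"mt_pair"`.
#' @param overrides named list of protocol fields to replace. The special
#'   override `n_echoes` regenerates the echo-time grid (log-spaced over
#'   the default 12--600 ms range) with the requested number of echoes.
#' @return an object of class `mpmri_protocol`: a list with the sequence
#'   timing fields for the given kind, the acquisition count `n_acq`, and
#'   the shared `geometry` (FOV 21 mm, 128 x 128 matrix, 1.25 mm slice).
#' @examples
#' p <- make_protocol("t2map")
#' length(p$te_ms)                    # 50 echoes
#' make_protocol("dwi_female")$b_values
#' @export
make_protocol <- function(kind = c("t2map", "dwi_male", "dwi_female", "mt_pair"),
                          overrides = list()) {
  kind <- match.arg(kind)
  geometry <- list(fov_mm = 21, matrix = 128L, slice_thickness_mm = 1.25)
  proto <- switch(kind,
    t2map = list(
      kind = "t2map", tr_ms = 5000,
      te_ms = exp(seq(log(12), log(600), length.out = 50)),
      geometry = geometry),
    dwi_male = list(
      kind = "dwi", tr_ms = 3000, te_ms = 31,
      b_values = seq(200, 2000, length.out = 9),
      delta_ms = 4, Delta_ms = 20, n_directions = 3L,
      geometry = geometry),
    dwi_female = list(
      kind = "dwi", tr_ms = 3000, te_ms = 31,
      b_values = c(300, 750, 1200),
      delta_ms = 4, Delta_ms = 20, n_directions = 3L,
      geometry = geometry),
    mt_pair = list(
      kind = "mt_pair", tr_ms = 2500, te_ms = 9.8,
      mt_pulse = list(n_pulses = 50, bandwidth_hz = 550, length_ms = 5,
                      power_ut = 5.5, offset_hz = 1500),
      geometry = geometry)
  )

  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be a named list")
    if (!is.null(overrides$n_echoes)) {
      if (proto$kind != "t2map") stop("n_echoes only applies to t2map protocols")
      n <- overrides$n_echoes
      if (n < 2) stop("n_echoes must be >= 2")
      proto$te_ms <- exp(seq(log(12), log(600), length.out = n))
      overrides$n_echoes <- NULL
    }
    known <- union(names(proto), c("te_ms", "b_values"))
    bad <- setdiff(names(overrides), known)
    if (length(bad)) stop("unknown protocol field(s): ", paste(bad, collapse = ", "))
    proto[names(overrides)] <- overrides
  }

  if (any(proto$te_ms <= 0)) stop("echo times must be positive")
  if (!is.null(proto$b_values)) {
    if (any(proto$b_values <= 0)) stop("b-values must be positive")
    if (anyDuplicated(proto$b_values)) stop("b-values must be distinct")
  }
  proto$n_acq <- switch(proto$kind,
    t2map = length(proto$te_ms),
    dwi = length(proto$b_values),
    mt_pair = 2L)
  class(proto) <- "mpmri_protocol"
  proto
}

#' @export
print.mpmri_protocol <- function(x, ...) {
  cat("<mpmri_protocol>", x$kind, "-", x$n_acq, "acquisitions\n")
  cat("  geometry: FOV", x$geometry$fov_mm, "mm, matrix", x$geometry$matrix,
      "(", round(voxel_size_um(x), 1), "um in-plane ), slice",
      x$geometry$slice_thickness_mm, "mm\n")
  invisible(x)
}

#' In-plane voxel size of a protocol
#'
#' @param protocol an `mpmri_protocol` (or any list with a `geometry` field).
#' @return in-plane voxel size in micrometres (FOV / matrix).
#' @export
voxel_size_um <- function(protocol) {
  g <- protocol$geometry
  g$fov_mm / g$matrix * 1000
}

#' Gyromagnetic ratio of the proton, rad s^-1 T^-1
#' @export
GAMMA_PROTON <- 2.6752218744e8

#' Diffusion b-value from gradient timings
#'
#' Computes the diffusion weighting b = gamma^2 delta^2 G^2 (Delta - delta/3)
#' for a pulsed-gradient spin-echo experiment, with the unit bookkeeping done
#' internally (timings in ms, gradient strength in mT/m, b in s mm^-2).
#'
#' @param G gradient strength, mT/m.
#' @param delta_ms gradient pulse duration, ms.
#' @param Delta_ms gradient separation, ms.
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1.
#' @return b-value in s mm^-2.
#' @examples
#' compute_b_value(216, 4, 20)  # about 1000 s mm^-2
#' @export
compute_b_value <- function(G, delta_ms, Delta_ms, gamma = GAMMA_PROTON) {
  if (any(G < 0) || delta_ms < 0 || Delta_ms < 0 || gamma < 0)
    stop("all inputs must be non-negative")
  if (Delta_ms <= delta_ms / 3)
    stop("Delta must exceed delta/3 (effective diffusion time must be positive)")
  # SI throughout (s, T/m) gives b in s/m^2; 1 m^2 = 1e6 mm^2
  delta <- delta_ms * 1e-3
  Delta <- Delta_ms * 1e-3
  g_si <- G * 1e-3
  b_si <- gamma^2 * delta^2 * g_si^2 * (Delta - delta / 3)
  b_si / 1e6
}

#' Gradient strength achieving a requested b-value
#'
#' Inverse of [compute_b_value()]: solves for G given b and the timings.
#'
#' @param b target b-value, s mm^-2.
#' @inheritParams compute_b_value
#' @return gradient strength in mT/m.
#' @export
solve_gradient_for_b <- function(b, delta_ms, Delta_ms, gamma = GAMMA_PROTON) {
  if (any(b < 0)) stop("b must be non-negative")
  if (Delta_ms <= delta_ms / 3)
    stop("Delta must exceed delta/3 (effective diffusion time must be positive)")
  delta <- delta_ms * 1e-3
  Delta <- Delta_ms * 1e-3
  b_si <- b * 1e6
  g_si <- sqrt(b_si / (gamma^2 * delta^2 * (Delta - delta / 3)))
  g_si * 1e3
}
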