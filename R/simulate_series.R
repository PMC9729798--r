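#' Simulate an acquired image series from a phantom
#'
#' Generates the noiseless signal for every voxel under the protocol's
#' signal model and applies the requested noise model per acquisition:
#' \itemize{
#'   \item T2 mapping: S(TE) = S0 exp(-TE / T2)
#'   \item diffusion: S(b) = S0 exp(-b ADC), with b in s mm^-2 and the
#'     ADC ground truth (um^2/s) converted to mm^2/s
#'   \item magnetization transfer: the off acquisition is S0 and the on
#'     acquisition S0 (1 - MTR/100)
#' }
#' Rician noise (the default for magnitude MRI) replaces the signal S by
#' sqrt((S + sigma Z1)^2 + (sigma Z2)^2); Gaussian noise adds sigma Z.
#'
#' @param phantom an [make_phantom()] object.
#' @param protocol an [make_protocol()] object.
#' @param noise_sigma noise standard deviation, a.u. (same scale as S0).
#' @param noise_model one of `"rician"`, `"gaussian"`, `"none"`.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return object of class `mpmri_series`: list with `data` (rows x cols x
#'   n_acquisitions array), `protocol`, and the phantom `geometry`.
#' @examples
#' ph <- make_phantom()
#' s <- simulate_series(ph, make_protocol("t2map"), noise_sigma = 0)
#' dim(s$data)
#' @export
simulate_series <- function(phantom, protocol,
                            noise_sigma = 0,
                            noise_model = c("rician", "gaussian", "none"),
                            seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (!inherits(phantom, "mpmri_phantom")) stop("phantom must be an mpmri_phantom")
  if (!inherits(protocol, "mpmri_protocol")) stop("protocol must be an mpmri_protocol")
  if (!is.null(protocol$geometry$matrix) &&
      protocol$geometry$matrix != nrow(phantom$label))
    stop("phantom and protocol geometries disagree")

  s0 <- phantom_param_image(phantom, "S0")
  n <- nrow(phantom$label)
  sig <- switch(protocol$kind,
    t2map = {
      t2 <- phantom_param_image(phantom, "T2_ms")
      inv_t2 <- ifelse(t2 > 0, 1 / t2, 0)
      vapply(protocol$te_ms, function(te) s0 * exp(-te * inv_t2),
             matrix(0, n, n))
    },
    dwi = {
      adc_mm2s <- phantom_param_image(phantom, "ADC_um2s") * 1e-6
      vapply(protocol$b_values, function(b) s0 * exp(-b * adc_mm2s),
             matrix(0, n, n))
    },
    mt_pair = {
      mtr <- phantom_param_image(phantom, "MTR_percent")
      array(c(s0, s0 * (1 - mtr / 100)), c(n, n, 2))
    },
    stop("unsupported protocol kind: ", protocol$kind))
  dim(sig) <- c(n, n, protocol$n_acq)

  if (noise_model != "none" && noise_sigma > 0) {
    sig <- with_seed(seed, add_acquisition_noise(sig, noise_sigma, noise_model))
  }
  structure(list(data = sig, protocol = protocol, geometry = phantom$geometry),
            class = "mpmri_series")
}

#' Apply Gaussian or Rician noise to a signal array
#'
#' @param signal numeric array of noiseless signal values.
#' @param sigma noise standard deviation (per real/imaginary channel for
#'   the Rician model).
#' @param model `"rician"` or `"gaussian"`.
#' @return array of the same shape with noise applied.
#' @export
add_acquisition_noise <- function(signal, sigma, model = c("rician", "gaussian")) {
  model <- match.arg(model)
  if (sigma < 0) stop("sigma must be >= 0")
  z1 <- array(stats::rnorm(length(signal), sd = sigma), dim(signal) %||% length(signal))
  if (model == "gaussian") return(signal + z1)
  z2 <- array(stats::rnorm(length(signal), sd = sigma), dim(signal) %||% length(signal))
  sqrt((signal + z1)^2 + z2^2)
}

#' @export
print.mpmri_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<mpmri_series>", x$protocol$kind, ":", d[1], "x", d[2], "x", d[3],
      "acquisitions\n")
  invisible(x)
}
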