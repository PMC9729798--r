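#' Synthetic metabolite basis set
#'
#' Builds a basis of prototypical 1H spectra for the cerebral metabolites
#' quantified in the study (Cr, PCr, NAA, Lac, mI, Tau, Glc, GABA, Cho,
#' GPC, PCh, Glu, Gln, Gly, Ala, Asp, acetate, mobile-lipid and
#' macromolecule signals). Each metabolite is a mixture of Lorentzian
#' lines at its characteristic chemical shifts, normalised to unit area
#' on a shared ppm grid. The line positions are textbook values; the
#' basis is synthetic, not a measured acquisition.
#'
#' @param ppm_range chemical-shift range (ppm). The default upper end
#'   leaves a signal-free window above 4.2 ppm for noise estimation.
#' @param n_points grid length.
#' @param linewidth Lorentzian half-width at half-maximum, ppm.
#' @param metabolites subset of metabolite names to include.
#' @return object of class `mpmri_basis`: list with `ppm`, `basis`
#'   (n_points x n_metabolites matrix), `metabolites`.
#' @export
make_basis_set <- function(ppm_range = c(0.2, 4.5), n_points = 2048,
                           linewidth = 0.02, metabolites = NULL) {
  peaks <- list(
    Ace    = c(1.91),
    Ala    = c(1.47),
    Asp    = c(2.68, 2.80),
    Cho    = c(3.19),
    Cr     = c(3.03, 3.93),
    GABA   = c(1.89, 2.29, 3.01),
    Glc    = c(3.23, 3.40, 3.80),
    Gln    = c(2.14, 2.45),
    Glu    = c(2.08, 2.35),
    Gly    = c(3.55),
    GPC    = c(3.21),
    Lac    = c(1.33, 4.10),
    mI     = c(3.27, 3.52, 3.61),
    NAA    = c(2.01),
    PCh    = c(3.22),
    PCr    = c(3.03, 3.95),
    Tau    = c(3.25, 3.42),
    Lip09  = c(0.90),
    Lip13a = c(1.28),
    Lip20  = c(2.02),
    M14    = c(1.40)
  )
  if (!is.null(metabolites)) {
    unknown <- setdiff(metabolites, names(peaks))
    if (length(unknown)) stop("unknown metabolite(s): ", paste(unknown, collapse = ", "))
    peaks <- peaks[metabolites]
  }
  ppm <- seq(ppm_range[1], ppm_range[2], length.out = n_points)
  dppm <- ppm[2] - ppm[1]
  lorentz <- function(centers) {
    y <- rowSums(vapply(centers,
      function(c0) linewidth^2 / (linewidth^2 + (ppm - c0)^2),
      numeric(n_points)))
    y / (sum(y) * dppm)                    # unit area
  }
  basis <- vapply(peaks, lorentz, numeric(n_points))
  structure(list(ppm = ppm, basis = basis, metabolites = names(peaks)),
            class = "mpmri_basis")
}

#' @export
print.mpmri_basis <- function(x, ...) {
  cat("<mpmri_basis>", length(x$metabolites), "metabolites on",
      length(x$ppm), "ppm points in [", min(x$ppm), ",", max(x$ppm), "]\n")
  invisible(x)
}

#' Simulate 1-D spectra as linear combinations of basis spectra
#'
#' Each spectrum is `sum_i conc_i basis_i + baseline + noise`, with a
#' smooth quadratic baseline of the given amplitude (zero by default so
#' that fitting tests are exact) and i.i.d. Gaussian noise. The
#' generating concentrations are stored in each record as `truth`.
#'
#' @param basis an [make_basis_set()] object.
#' @param true_conc named non-negative amounts; names must be basis
#'   metabolites (missing metabolites have amount 0).
#' @param noise_sigma Gaussian noise standard deviation.
#' @param baseline_amplitude scale of the quadratic baseline.
#' @param n_spectra number of replicate spectra.
#' @param seed integer seed.
#' @param metadata optional list (animal_id, sex, diet, region) copied
#'   into every record.
#' @return list of `mpmri_spectrum` records: `ppm`, `intensity`,
#'   `metadata`, `truth`.
#' @export
simulate_spectra <- function(basis, true_conc, noise_sigma = 0,
                             baseline_amplitude = 0, n_spectra = 1,
                             seed = NULL, metadata = list()) {
  stopifnot(inherits(basis, "mpmri_basis"))
  unknown <- setdiff(names(true_conc), basis$metabolites)
  if (length(unknown)) stop("unknown metabolite(s): ", paste(unknown, collapse = ", "))
  if (any(true_conc < 0)) stop("amounts must be >= 0")
  conc <- stats::setNames(numeric(length(basis$metabolites)), basis$metabolites)
  conc[names(true_conc)] <- true_conc
  clean <- as.vector(basis$basis %*% conc)
  u <- seq(-1, 1, length.out = length(basis$ppm))
  baseline <- baseline_amplitude * (0.5 - 0.3 * u + 0.4 * u^2)
  with_seed(seed, {
    lapply(seq_len(n_spectra), function(i) {
      y <- clean + baseline +
        if (noise_sigma > 0) stats::rnorm(length(clean), sd = noise_sigma) else 0
      structure(list(ppm = basis$ppm, intensity = y,
                     metadata = metadata, truth = conc),
                class = "mpmri_spectrum")
    })
  })
}
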