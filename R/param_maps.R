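#' @title Parametric map container
#' @description A fitted per-voxel parameter image with a validity mask and
#'   per-voxel goodness of fit. Invalid voxels (non-converged fits,
#'   non-physical estimates, empty voxels) carry `NA` in `values` and are
#'   excluded from all downstream statistics.
#' @param parameter map name: "T2", "ADC", "MTR" or "S0".
#' @param values numeric matrix of fitted values (NA where invalid).
#' @param valid logical matrix.
#' @param r2 numeric matrix of per-voxel R^2 (NA where undefined).
#' @param units unit string recorded in metadata.
#' @return object of class `mpmri_map`.
#' @export
param_map <- function(parameter, values, valid, r2 = NULL, units = "") {
  values[!valid] <- NA_real_
  structure(list(parameter = parameter, values = values, valid = valid,
                 r2 = r2, units = units),
            class = "mpmri_map")
}

#' @export
print.mpmri_map <- function(x, ...) {
  cat("<mpmri_map>", x$parameter, "(", x$units, "):",
      sum(x$valid), "valid /", length(x$valid), "voxels\n")
  invisible(x)
}

# Vectorised bounded Levenberg-Marquardt for y = S0 * exp(-r * x), one
# (S0, r) pair per row of Y. Log-linear OLS initialisation (exact on
# noiseless data), projected steps onto [r_min, r_max] x [0, Inf).
fit_monoexp_rows <- function(Y, x, r_min, r_max, rel_tol = 1e-8, maxit = 200) {
  nv <- nrow(Y); na_ <- length(x)
  stopifnot(ncol(Y) == na_)

  # initialisation: OLS on log(signal), guarded for non-positive values
  eps <- max(abs(Y)) * 1e-12 + 1e-300
  L <- log(pmax(Y, eps))
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  r0 <- -as.vector(L %*% xc) / sxx
  r0 <- pmin(pmax(r0, r_min), r_max)
  ls0 <- rowMeans(L) + r0 * mean(x)
  s0 <- pmax(exp(pmin(ls0, 700)), 0)

  lam <- rep(1e-3, nv)
  conv <- rep(FALSE, nv)
  E <- exp(-outer(r0, x))
  Fv <- s0 * E
  sse <- rowSums((Fv - Y)^2)

  active <- which(!conv)
  for (it in seq_len(maxit)) {
    if (!length(active)) break
    Ea <- E[active, , drop = FALSE]
    Ya <- Y[active, , drop = FALSE]
    s0a <- s0[active]; ra <- r0[active]
    res <- s0a * Ea - Ya
    J2f <- -s0a * Ea * rep(x, each = length(active))   # d/dr
    a11 <- rowSums(Ea * Ea)
    a12 <- rowSums(Ea * J2f)
    a22 <- rowSums(J2f * J2f)
    g1 <- rowSums(Ea * res)
    g2 <- rowSums(J2f * res)
    d11 <- a11 * (1 + lam[active])
    d22 <- a22 * (1 + lam[active]) + 1e-300
    det <- d11 * d22 - a12^2
    det[abs(det) < 1e-300] <- 1e-300
    ds0 <- -( d22 * g1 - a12 * g2) / det
    dr  <- -(-a12 * g1 + d11 * g2) / det
    s0n <- pmax(s0a + ds0, 0)
    rn <- pmin(pmax(ra + dr, r_min), r_max)
    En <- exp(-outer(rn, x))
    ssen <- rowSums((s0n * En - Ya)^2)
    better <- ssen <= sse[active]
    idx <- active[better]
    reldrop <- (sse[idx] - ssen[better]) / (sse[idx] + 1e-30)
    s0[idx] <- s0n[better]; r0[idx] <- rn[better]
    E[idx, ] <- En[better, , drop = FALSE]
    sse[idx] <- ssen[better]
    lam[idx] <- lam[idx] / 3
    lam[active[!better]] <- lam[active[!better]] * 8
    conv[idx[reldrop < rel_tol]] <- TRUE
    conv[active[!better][lam[active[!better]] > 1e10]] <- TRUE
    active <- which(!conv)
  }

  sst <- rowSums((Y - rowMeans(Y))^2)
  r2 <- ifelse(sst > 0, 1 - sse / sst, NA_real_)
  list(s0 = s0, rate = r0, converged = conv, r2 = r2, sse = sse)
}

#' Fit a voxelwise T2 map from a multi-echo series
#'
#' Fits S(TE) = S0 exp(-TE / T2) in every voxel by log-linear least
#' squares refined with bounded Levenberg-Marquardt on the exponential
#' model. Voxels whose fit does not converge, whose amplitude is not
#' positive, or whose T2 estimate hits the physical bounds (1-2000 ms)
#' are flagged invalid; the degenerate no-decay voxel (T2 at the upper
#' bound) is invalid rather than silently retained.
#'
#' @param series an `mpmri_series` from a `t2map` protocol with >= 3 echoes.
#' @return list with elements `t2` and `s0`, both [param_map()] objects
#'   (T2 in ms, S0 in a.u.).
#' @export
fit_t2_map <- function(series) {
  stopifnot(inherits(series, "mpmri_series"))
  p <- series$protocol
  if (p$kind != "t2map") stop("protocol kind must be t2map")
  if (length(p$te_ms) < 3) stop("T2 fitting needs at least 3 echoes")
  d <- dim(series$data)
  Y <- matrix(series$data, d[1] * d[2], d[3])
  fit <- fit_monoexp_rows(Y, p$te_ms, r_min = 1 / 2000, r_max = 1)
  t2 <- 1 / fit$rate
  valid <- fit$converged & fit$s0 > 0 & is.finite(t2) &
    fit$rate > 1 / 2000 & fit$rate < 1 & rowSums(abs(Y)) > 0
  shape <- function(v) matrix(v, d[1], d[2])
  list(
    t2 = param_map("T2", shape(t2), shape(valid), shape(fit$r2), "ms"),
    s0 = param_map("S0", shape(fit$s0), shape(valid), shape(fit$r2), "a.u.")
  )
}

#' Fit a voxelwise ADC map from a diffusion-weighted series
#'
#' Fits S(b) = S0 exp(-b ADC) per voxel (b in s mm^-2, ADC reported in
#' um^2/s). When the series holds one volume per b-value and direction,
#' the three orthogonal-direction signals are combined per b-value before
#' fitting (arithmetic mean by default). An ADC of exactly zero (no
#' decay) is a legal estimate left to the downstream 0 < ADC filter;
#' estimates at the upper physical bound (4000 um^2/s) are invalid.
#'
#' @param series an `mpmri_series` from a dwi protocol with >= 2 distinct
#'   b-values.
#' @param average `"arithmetic"` or `"geometric"` combination across
#'   gradient directions (only used when per-direction volumes are
#'   present).
#' @return list with elements `adc` and `s0` [param_map()] objects.
#' @export
fit_adc_map <- function(series, average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  stopifnot(inherits(series, "mpmri_series"))
  p <- series$protocol
  if (p$kind != "dwi") stop("protocol kind must be dwi")
  b <- p$b_values
  if (length(b) < 2) stop("ADC fitting needs at least 2 b-values")
  if (anyDuplicated(b)) stop("b-values must be distinct")
  d <- dim(series$data)
  Y <- matrix(series$data, d[1] * d[2], d[3])
  nd <- p$n_directions %||% 1L
  if (d[3] == length(b) * nd && nd > 1) {
    # volumes ordered direction-major within each b
    Y <- vapply(seq_along(b), function(i) {
      block <- Y[, ((i - 1) * nd + 1):(i * nd), drop = FALSE]
      if (average == "arithmetic") rowMeans(block)
      else exp(rowMeans(log(pmax(block, 1e-300))))
    }, numeric(d[1] * d[2]))
  } else if (d[3] != length(b)) {
    stop("series has ", d[3], " volumes but the protocol implies ",
         length(b), " or ", length(b) * nd)
  }
  fit <- fit_monoexp_rows(Y, b, r_min = 0, r_max = 4000e-6)
  adc <- fit$rate * 1e6
  valid <- fit$converged & fit$s0 > 0 & fit$rate < 4000e-6 &
    rowSums(abs(Y)) > 0
  shape <- function(v) matrix(v, d[1], d[2])
  list(
    adc = param_map("ADC", shape(adc), shape(valid), shape(fit$r2), "um^2/s"),
    s0 = param_map("S0", shape(fit$s0), shape(valid), shape(fit$r2), "a.u.")
  )
}

#' Magnetization transfer ratio map
#'
#' MTR = (S0 - S_MT) / S0 * 100 per voxel, where S0 is the saturation-off
#' acquisition and S_MT the saturation-on acquisition. Voxels with S0 = 0
#' are invalid. Negative MTR values are retained in the map (the MTR > 0
#' retention filter is applied later, at the ROI stage).
#'
#' @param series_off MT-off acquisition: an `mpmri_series`, or a numeric
#'   matrix. An `mt_pair` series holding both volumes may be passed alone.
#' @param series_on MT-on acquisition (matrix or single-volume series);
#'   omit when `series_off` is a two-volume `mt_pair` series.
#' @return a [param_map()] of MTR in percent.
#' @export
compute_mtr_map <- function(series_off, series_on = NULL) {
  as_img <- function(x, vol) {
    if (inherits(x, "mpmri_series")) x$data[, , vol] else as.matrix(x)
  }
  if (is.null(series_on)) {
    if (!(inherits(series_off, "mpmri_series") && dim(series_off$data)[3] == 2))
      stop("series_on missing and series_off is not a two-volume mt_pair series")
    s_on <- as_img(series_off, 2); s_off <- as_img(series_off, 1)
  } else {
    s_off <- as_img(series_off, 1); s_on <- as_img(series_on, 1)
  }
  if (!all(dim(s_off) == dim(s_on))) stop("geometries of the two series differ")
  valid <- s_off != 0
  mtr <- matrix(NA_real_, nrow(s_off), ncol(s_off))
  mtr[valid] <- (s_off[valid] - s_on[valid]) / s_off[valid] * 100
  param_map("MTR", mtr, valid, units = "percent")
}
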