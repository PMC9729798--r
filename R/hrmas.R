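#' Linear-combination fit of a spectrum against a basis set
#'
#' Solves a non-negative least-squares problem expressing the spectrum as
#' a linear combination of the basis spectra plus a low-order polynomial
#' baseline (whose coefficients are unconstrained in sign). The relative
#' precision of each amount, `sd_percent = 100 SE / amount`, comes from
#' the least-squares covariance over the active columns with the noise
#' variance estimated in a signal-free ppm window.
#'
#' @param spectrum an `mpmri_spectrum` (list with `ppm`, `intensity`).
#' @param basis an [make_basis_set()] object; resampled onto the spectrum
#'   grid by linear interpolation when the grids differ.
#' @param baseline_order polynomial baseline order (default 2; negative
#'   disables the baseline).
#' @param noise_window ppm interval assumed free of metabolite signal,
#'   used for the noise estimate.
#' @return data frame: metabolite, amount, SE, sd_percent (Inf where the
#'   amount is zero).
#' @export
fit_linear_combination <- function(spectrum, basis, baseline_order = 2,
                                   noise_window = c(4.2, 4.5)) {
  stopifnot(inherits(basis, "mpmri_basis"))
  ppm <- spectrum$ppm
  y <- spectrum$intensity
  if (any(diff(ppm) <= 0)) stop("ppm axis must be strictly increasing")
  B <- if (isTRUE(all.equal(ppm, basis$ppm))) basis$basis
       else apply(basis$basis, 2, function(col)
         stats::approx(basis$ppm, col, xout = ppm, rule = 2)$y)
  m <- ncol(B)
  if (qr(B)$rank < m)
    stop("rank-deficient basis: metabolite spectra are collinear")

  # signed polynomial columns let NNLS fit an unconstrained baseline
  P <- NULL
  if (baseline_order >= 0) {
    u <- seq(-1, 1, length.out = length(ppm))
    P <- vapply(0:baseline_order, function(k) u^k, numeric(length(ppm)))
  }
  A <- cbind(B, P, -P)
  sol <- pracma::lsqnonneg(A, y)
  x <- sol$x
  amounts <- x[seq_len(m)]

  inwin <- ppm >= noise_window[1] & ppm <= noise_window[2]
  if (sum(inwin) < 10)
    stop("no usable signal-free window in [", noise_window[1], ", ",
         noise_window[2], "] ppm")
  resid <- y - as.vector(A %*% x)
  sigma <- stats::sd(resid[inwin])

  # covariance over the active set (unconstrained at the solution)
  active <- which(x > 0)
  se <- rep(NA_real_, m)
  if (length(active)) {
    Aa <- A[, active, drop = FALSE]
    xtx_inv <- tryCatch(solve(crossprod(Aa)), error = function(e) NULL)
    if (!is.null(xtx_inv)) {
      se_active <- sigma * sqrt(pmax(diag(xtx_inv), 0))
      met_active <- active[active <= m]
      se[met_active] <- se_active[match(met_active, active)]
    }
  }
  sd_percent <- ifelse(amounts > 0, 100 * se / amounts, Inf)
  data.frame(metabolite = basis$metabolites, amount = amounts,
             SE = se, sd_percent = sd_percent, row.names = NULL)
}

#' Ratios to total creatine
#'
#' Divides every metabolite amount by the total creatine signal
#' (Cr + PCr) and appends the composite sums reported in the study
#' (Cho+GPC+PCh, mI+Gly, Cr+PCr, Glu+Gln) where their components are
#' present.
#'
#' @param amounts named numeric vector of amounts, or the data frame
#'   returned by [fit_linear_combination()].
#' @return data frame: metabolite, ratio_to_tcr. The Cr+PCr row is 1 by
#'   construction.
#' @export
to_tcr_ratios <- function(amounts) {
  if (is.data.frame(amounts))
    amounts <- stats::setNames(amounts$amount, amounts$metabolite)
  if (!all(c("Cr", "PCr") %in% names(amounts)))
    stop("Cr and PCr amounts are required for the total-creatine reference")
  tcr <- amounts[["Cr"]] + amounts[["PCr"]]
  if (tcr <= 0) stop("Cr + PCr must be positive")
  ratios <- amounts / tcr
  composites <- list("Cho+GPC+PCh" = c("Cho", "GPC", "PCh"),
                     "mI+Gly" = c("mI", "Gly"),
                     "Cr+PCr" = c("Cr", "PCr"),
                     "Glu+Gln" = c("Glu", "Gln"))
  comp <- vapply(composites, function(parts) {
    if (all(parts %in% names(amounts))) sum(amounts[parts]) / tcr else NA_real_
  }, numeric(1))
  out <- data.frame(metabolite = c(names(ratios), names(comp)),
                    ratio_to_tcr = c(unname(ratios), unname(comp)),
                    row.names = NULL)
  out[!is.na(out$ratio_to_tcr), , drop = FALSE]
}

#' Precision filter on fitted metabolites
#'
#' Keeps rows whose relative standard deviation is at or below the
#' threshold (boundary inclusive, default 20 percent), the quality filter
#' applied before group statistics.
#'
#' @param table data frame with an `sd_percent` column.
#' @param threshold maximum sd_percent retained.
#' @return the filtered table.
#' @export
filter_sd <- function(table, threshold = 20) {
  stopifnot("sd_percent" %in% names(table))
  out <- table[!is.na(table$sd_percent) & table$sd_percent <= threshold, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Choose between the additive and interaction metabolite models
#'
#' Fits `ratio ~ diet + area` and `ratio ~ diet + area + diet:area` as
#' linear mixed models with a mouse random intercept (one spectrum per
#' mouse x area means the area-within-mouse component is not separable
#' from the residual), compares them by likelihood-ratio test at
#' alpha = 0.05, and refits the chosen model by REML.
#'
#' @param table data frame: animal_id, diet, area (or region), metabolite,
#'   ratio_to_tcr.
#' @param metabolite which metabolite to model.
#' @param alpha LRT level for including the interaction.
#' @return list: `chosen` ("diet+area" or "diet+area+diet:area"), `fit`
#'   (REML `lme`), `lrt_p`, `aic` (both ML fits), `data`.
#' @export
metabolite_model_compare <- function(table, metabolite, alpha = 0.05) {
  d <- as.data.frame(table)
  if ("region" %in% names(d) && !"area" %in% names(d)) d$area <- d$region
  d <- d[d$metabolite == metabolite, , drop = FALSE]
  need <- c("animal_id", "diet", "area", "ratio_to_tcr")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (length(unique(d$diet)) < 2 || length(unique(d$area)) < 2)
    stop("need at least 2 diets and 2 areas")
  d$diet <- factor(d$diet); d$area <- factor(d$area)
  d$animal_id <- factor(d$animal_id)
  stats::contrasts(d$diet) <- stats::contr.sum(nlevels(d$diet))
  stats::contrasts(d$area) <- stats::contr.sum(nlevels(d$area))
  ctl <- nlme::lmeControl(maxIter = 100, msMaxIter = 200, returnObject = TRUE)
  m0 <- nlme::lme(ratio_to_tcr ~ diet + area, random = ~ 1 | animal_id,
                  data = d, method = "ML", control = ctl)
  m1 <- nlme::lme(ratio_to_tcr ~ diet + area + diet:area,
                  random = ~ 1 | animal_id, data = d, method = "ML",
                  control = ctl)
  lrt <- stats::anova(m0, m1)
  p <- lrt[["p-value"]][2]
  chosen <- if (!is.na(p) && p < alpha) "diet+area+diet:area" else "diet+area"
  form <- if (chosen == "diet+area") ratio_to_tcr ~ diet + area
          else ratio_to_tcr ~ diet + area + diet:area
  refit <- nlme::lme(form, random = ~ 1 | animal_id, data = d,
                     method = "REML", control = ctl)
  list(chosen = chosen, fit = refit, lrt_p = p,
       aic = c(additive = stats::AIC(m0), interaction = stats::AIC(m1)),
       data = d)
}

#' Type III tests and per-area post-hoc diet contrasts for a metabolite
#'
#' Runs the marginal Wald chi-square tests of the chosen metabolite model
#' and, when the diet:area interaction is included, tests the diet effect
#' within each area with a Bonferroni correction over the 4 areas.
#'
#' @param model result of [metabolite_model_compare()].
#' @return list: `anova` (term, chisq, df, p) and `posthoc` (area,
#'   estimate, SE, df, t, p_raw, p_adjusted; NULL for the additive model).
#' @export
metabolite_tests <- function(model) {
  a <- car::Anova(model$fit, type = 3)
  keep <- rownames(a) != "(Intercept)"
  anova_tab <- data.frame(term = rownames(a)[keep], chisq = a$Chisq[keep],
                          df = a$Df[keep], p = a[["Pr(>Chisq)"]][keep],
                          row.names = NULL)
  posthoc <- NULL
  if (model$chosen == "diet+area+diet:area") {
    em <- emmeans::emmeans(model$fit, ~ diet | area, data = model$data)
    ct <- summary(emmeans::contrast(em, "pairwise"), adjust = "none")
    n_areas <- length(unique(ct$area))
    posthoc <- data.frame(area = ct$area, estimate = ct$estimate, SE = ct$SE,
                          df = ct$df, t = ct$t.ratio, p_raw = ct$p.value,
                          p_adjusted = pmin(ct$p.value * n_areas, 1),
                          row.names = NULL)
  }
  list(anova = anova_tab, posthoc = posthoc)
}
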