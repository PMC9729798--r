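#' The sequential mixed-model ladder
#'
#' Returns the ordered chain of nine nested model specifications used for
#' the longitudinal MR analysis: from the baseline model B (random
#' components only) through area (A), time (AT), a per-mouse random time
#' slope (ATrs), diet (ATrsD), and the time:area, diet:time, diet:area
#' and diet:area:time interactions. Every model keeps the shared random
#' structure (mouse intercept, area-within-mouse intercept, AR(1)
#' residual correlation over time points within mouse x area); models
#' from ATrs onward add the per-mouse slope in rescaled day. Each spec's
#' fixed terms are a superset of its predecessor's.
#'
#' @return list of `mpmri_model_spec` objects, in ladder order.
#' @export
model_ladder <- function() {
  steps <- list(
    B                     = character(0),
    A                     = "area",
    AT                    = c("area", "time"),
    ATrs                  = c("area", "time"),
    ATrsD                 = c("area", "time", "diet"),
    ATrsD.TA              = c("area", "time", "diet", "area:time"),
    ATrsD.TA.DT           = c("area", "time", "diet", "area:time", "diet:time"),
    ATrsD.TA.DT.DA        = c("area", "time", "diet", "area:time", "diet:time",
                              "diet:area"),
    ATrsD.TA.DT.DA.DAT    = c("area", "time", "diet", "area:time", "diet:time",
                              "diet:area", "diet:area:time")
  )
  mapply(function(name, terms) {
    structure(list(name = name, fixed = terms,
                   random_slope = grepl("rs", name, fixed = TRUE)),
              class = "mpmri_model_spec")
  }, names(steps), steps, SIMPLIFY = FALSE)
}

#' Look up a ladder model by name
#'
#' Accepts the canonical names and the alternative interaction spellings
#' that put the factor letters in the other order (e.g. `ATrsD.AT` for
#' `ATrsD.TA`, `ATrsD.AT.DT.DA` for `ATrsD.TA.DT.DA`).
#'
#' @param name model name string.
#' @return the matching `mpmri_model_spec`.
#' @export
ladder_spec <- function(name) {
  ladder <- model_ladder()
  canon <- function(x) {
    parts <- strsplit(x, ".", fixed = TRUE)[[1]]
    parts[-1] <- vapply(parts[-1],
      function(p) paste(sort(strsplit(p, "")[[1]]), collapse = ""), "")
    paste(parts, collapse = ".")
  }
  names(ladder) <- vapply(names(ladder), canon, "")
  spec <- ladder[[canon(name)]]
  if (is.null(spec)) stop("unknown ladder model: ", name)
  spec
}

# term translation from design language to data columns
fixed_formula <- function(spec) {
  map <- c(area = "region", time = "time_f", diet = "diet",
           "area:time" = "region:time_f", "diet:time" = "diet:time_f",
           "diet:area" = "diet:region", "diet:area:time" = "diet:region:time_f")
  rhs <- if (length(spec$fixed)) paste(map[spec$fixed], collapse = " + ") else "1"
  stats::as.formula(paste("log_value ~", rhs))
}

prepare_lme_data <- function(table, parameter = NULL) {
  d <- as.data.frame(table)
  if (!is.null(parameter)) d <- d[d$parameter == parameter, , drop = FALSE]
  if ("parameter" %in% names(d) && length(unique(d$parameter)) > 1)
    stop("table mixes parameters; pass `parameter` to select one")
  need <- c("animal_id", "diet", "day", "region", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- d[!is.na(d$value), , drop = FALSE]
  bad <- d$value <= 0
  if (any(bad))
    stop("non-positive response in rows ", paste(utils::head(which(bad), 5), collapse = ", "),
         " -- the log transform requires positive values")
  d$log_value <- log(d$value)
  d$animal_id <- factor(d$animal_id)
  d$region <- factor(d$region)
  d$diet <- factor(d$diet)
  d$time_f <- factor(d$day)
  d$day01 <- d$day / max(d$day)
  d$time_index <- as.integer(d$time_f)
  # sum-to-zero coding for valid type III marginal tests
  stats::contrasts(d$region) <- stats::contr.sum(nlevels(d$region))
  stats::contrasts(d$diet) <- stats::contr.sum(nlevels(d$diet))
  stats::contrasts(d$time_f) <- stats::contr.sum(nlevels(d$time_f))
  d
}

#' Fit one ladder model to an ROI table
#'
#' Fits the specified linear mixed-effects model to `log(value)` with
#' `nlme::lme`: random intercepts for mouse and for area within mouse
#' (plus, for "rs" models, a per-mouse random slope in day rescaled to
#' \[0, 1\], fitted with a diagonal covariance), and AR(1) residual
#' correlation over the time-point index within each mouse x area series.
#'
#' @param table long-format ROI table (one MR parameter).
#' @param spec an `mpmri_model_spec` (or a ladder model name).
#' @param method `"ML"` (for AIC comparison across fixed effects) or
#'   `"REML"` (for reporting the selected model).
#' @param parameter optional parameter to select from a mixed table.
#' @return object of class `mpmri_lme_fit`: list with `spec`, the `nlme`
#'   `fit`, `logLik`, `AIC`, `phi` (fitted AR(1) coefficient), variance
#'   components, `converged`, `n_obs`, `n_mice`, and the prepared data.
#' @export
fit_lme <- function(table, spec, method = c("ML", "REML"), parameter = NULL) {
  method <- match.arg(method)
  if (is.character(spec)) spec <- ladder_spec(spec)
  d <- prepare_lme_data(table, parameter)
  if (length(unique(d$animal_id[d$diet == levels(d$diet)[1]])) < 2 &&
      nlevels(d$diet) > 1)
    stop("need at least 2 animals per diet")
  random <- if (spec$random_slope)
    list(animal_id = nlme::pdDiag(~ day01), region = nlme::pdIdent(~ 1))
  else
    list(animal_id = nlme::pdIdent(~ 1), region = nlme::pdIdent(~ 1))
  fit <- try(nlme::lme(
    fixed = fixed_formula(spec), data = d, random = random,
    correlation = nlme::corAR1(form = ~ time_index | animal_id / region),
    method = method,
    control = nlme::lmeControl(maxIter = 100, msMaxIter = 200, niterEM = 50,
                               returnObject = TRUE)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(spec = spec, fit = NULL, logLik = NA_real_,
                          AIC = NA_real_, phi = NA_real_, varcomp = NULL,
                          converged = FALSE, n_obs = nrow(d),
                          n_mice = nlevels(d$animal_id), data = d,
                          method = method,
                          error = attr(fit, "condition")$message),
                     class = "mpmri_lme_fit"))
  }
  phi <- tryCatch(
    stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE)[[1]],
    error = function(e) NA_real_)
  structure(list(spec = spec, fit = fit,
                 logLik = as.numeric(stats::logLik(fit)),
                 AIC = stats::AIC(fit), phi = phi,
                 varcomp = nlme::VarCorr(fit),
                 converged = TRUE, n_obs = nrow(d),
                 n_mice = nlevels(d$animal_id), data = d, method = method),
            class = "mpmri_lme_fit")
}

#' @export
print.mpmri_lme_fit <- function(x, ...) {
  cat("<mpmri_lme_fit>", x$spec$name, "(", x$method, ")",
      if (x$converged) sprintf("AIC = %.2f, phi = %.3f", x$AIC, x$phi)
      else "did not converge", "\n")
  invisible(x)
}

#' AIC model selection over the ladder
#'
#' Fits every ladder model by maximum likelihood and returns the
#' converged model with the lowest AIC; within a tolerance of 1e-6 the
#' simpler (earlier) model wins.
#'
#' @param table long-format ROI table.
#' @param ladder list of specs, default [model_ladder()].
#' @param parameter optional parameter selector.
#' @return list with `best` (the winning `mpmri_lme_fit`, ML) and
#'   `aic_table` (data frame: model, AIC, logLik, converged).
#' @export
select_best_model <- function(table, ladder = model_ladder(), parameter = NULL) {
  fits <- lapply(ladder, function(s) fit_lme(table, s, "ML", parameter))
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  tab <- data.frame(model = vapply(fits, function(f) f$spec$name, ""),
                    AIC = aic,
                    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                    converged = conv, row.names = NULL)
  ok <- which(conv & is.finite(aic))
  if (length(ok) < 2) stop("fewer than 2 ladder models fitted successfully")
  best_idx <- ok[which(aic[ok] <= min(aic[ok]) + 1e-6)[1]]
  list(best = fits[[best_idx]], aic_table = tab)
}

#' Type III Wald tests of the fixed effects
#'
#' Marginal (type III) Wald chi-square test of every fixed term of a
#' fitted ladder model, computed under the sum-to-zero contrast coding
#' the fit uses.
#'
#' @param fit an `mpmri_lme_fit`.
#' @return data frame: term, chisq, df, p.
#' @export
anova_type3 <- function(fit) {
  stopifnot(inherits(fit, "mpmri_lme_fit"))
  if (!fit$converged) stop("fit did not converge")
  if (!length(fit$spec$fixed)) stop("model has no fixed effects to test")
  a <- car::Anova(fit$fit, type = 3)
  keep <- rownames(a) != "(Intercept)"
  data.frame(term = rownames(a)[keep],
             chisq = a$Chisq[keep], df = a$Df[keep],
             p = a[["Pr(>Chisq)"]][keep], row.names = NULL)
}

#' Dunnett-style adjustment from the joint distribution of contrasts
#'
#' Two-sided familywise-adjusted p-values for a set of contrasts against
#' a common baseline: for each statistic, 1 - P(max_j |T_j| < |t_i|)
#' under the joint multivariate t distribution with the given correlation
#' matrix. Falls back to seeded Monte Carlo if the integrator fails.
#'
#' @param t_stats vector of t statistics.
#' @param df residual degrees of freedom (Inf for normal).
#' @param corr correlation matrix of the statistics (default identity).
#' @param mc_draws draws for the Monte-Carlo fallback.
#' @param seed seed for the fallback.
#' @return vector of adjusted p-values.
#' @export
dunnett_adjust <- function(t_stats, df, corr = diag(length(t_stats)),
                           mc_draws = 1e5, seed = 1) {
  vapply(abs(t_stats), function(ti) {
    p <- tryCatch({
      pr <- with_seed(seed, mvtnorm::pmvt(
        lower = rep(-ti, length(t_stats)),
        upper = rep(ti, length(t_stats)),
        df = as.integer(round(df)), corr = corr,
        algorithm = mvtnorm::GenzBretz(abseps = 1e-5, maxpts = 250000)))
      1 - as.numeric(pr)
    }, error = function(e) NA_real_)
    if (is.na(p)) {
      p <- with_seed(seed, {
        z <- mvtnorm::rmvt(mc_draws, sigma = corr, df = round(df))
        mean(apply(abs(z), 1, max) >= ti)
      })
    }
    min(max(p, 0), 1)
  }, numeric(1))
}

#' Day-versus-baseline contrasts with Dunnett correction
#'
#' Estimated-marginal-means contrasts of every post-baseline day against
#' day 0, separately for each diet x region cell, adjusted for the 4
#' comparisons of a family through the joint multivariate t distribution
#' of the contrast statistics (Dunnett-style, `emmeans` "mvt").
#'
#' @param fit an `mpmri_lme_fit` whose model contains the time factor.
#' @param diet,region optional filters; default all cells.
#' @return data frame: diet, region, day, estimate (log scale), SE, df,
#'   t, p_raw, p_adjusted.
#' @export
time_contrasts <- function(fit, diet = NULL, region = NULL) {
  stopifnot(inherits(fit, "mpmri_lme_fit"))
  if (!fit$converged) stop("fit did not converge")
  if (!"time" %in% fit$spec$fixed) stop("model has no time effect")
  em <- emmeans::emmeans(fit$fit, ~ time_f | diet + region, data = fit$data)
  raw <- summary(emmeans::contrast(em, "trt.vs.ctrl", ref = 1, adjust = "none"))
  adj <- with_seed(1L,
    summary(emmeans::contrast(em, "trt.vs.ctrl", ref = 1, adjust = "mvt")))
  day <- as.numeric(sub("^time_f(\\d+) .*", "\\1", raw$contrast))
  out <- data.frame(diet = raw$diet, region = raw$region,
                    contrast = raw$contrast, day = day,
                    estimate = raw$estimate, SE = raw$SE, df = raw$df,
                    t = raw$t.ratio, p_raw = raw$p.value,
                    p_adjusted = adj$p.value, row.names = NULL)
  if (!is.null(diet)) out <- out[out$diet %in% diet, , drop = FALSE]
  if (!is.null(region)) out <- out[out$region %in% region, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Residual diagnostics of a mixed-model fit
#'
#' Normalized (whitened) residuals against fitted values and normal
#' quantiles, plus a Shapiro-Wilk normality summary, for the standard
#' residual checks of a longitudinal mixed model.
#'
#' @param fit an `mpmri_lme_fit`.
#' @return list with `table` (fitted, residual, theoretical quantile; one
#'   row per observation), `shapiro_p`, `mean_resid`, `se_mean`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "mpmri_lme_fit"))
  if (!fit$converged) stop("fit did not converge")
  r <- stats::resid(fit$fit, type = "normalized")
  f <- stats::fitted(fit$fit)
  qq <- stats::qnorm(stats::ppoints(length(r)))[rank(r, ties.method = "first")]
  sw <- if (length(r) >= 3 && length(r) <= 5000) stats::shapiro.test(r)$p.value
        else NA_real_
  list(table = data.frame(fitted = f, residual = r, theoretical = qq),
       shapiro_p = sw,
       mean_resid = mean(r),
       se_mean = stats::sd(r) / sqrt(length(r)))
}
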