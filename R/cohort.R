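#' Longitudinal cohort design for the mixed-model simulator
#'
#' Describes a two-diet, two-sex, five-time-point, four-region longitudinal
#' study with nested random effects and AR(1) serial correlation on the
#' log scale. Fixed effects are given as named increment vectors/matrices
#' on the log response; unnamed levels default to zero, so e.g. a design
#' with only `area` and `time` entries generates data with no diet effect.
#'
#' @param n_per_group animals per sex x diet cell; a single number or a
#'   named vector over diets (default the study sizes: 7 SD, 8 HFD).
#' @param diets,sexes,days,regions factor levels of the design. `days`
#'   must be strictly increasing and include the baseline day 0.
#' @param beta list of fixed-effect increments on the log scale:
#'   `intercept`, and optionally `area`, `time`, `diet` (named vectors),
#'   `area_time`, `diet_time`, `diet_area` (named matrices), and
#'   `diet_area_time` (named 3-d array). Defaults emulate regional T2
#'   differences with a mild time decline and a small diet offset.
#' @param sd_mouse,sd_area,sd_slope,sd_resid standard deviations of the
#'   mouse intercept, area-within-mouse intercept, per-mouse time slope
#'   (on day rescaled to \[0, 1\]), and the AR(1) residual, all on the
#'   log scale.
#' @param rho_ar AR(1) coefficient of residuals over successive time
#'   points within each mouse x area series; |rho_ar| < 1.
#' @param parameter label written into the output `parameter` column.
#' @param seed integer seed for [simulate_cohort()].
#' @return list of class `mpmri_cohort_design`.
#' @export
cohort_design <- function(n_per_group = c(SD = 7, HFD = 8),
                          diets = c("SD", "HFD"),
                          sexes = c("male", "female"),
                          days = c(0, 7, 14, 28, 70),
                          regions = c("hypothalamus", "hippocampus", "nac", "ila"),
                          beta = list(
                            intercept = log(45),
                            area = c(hypothalamus = 0, hippocampus = 0.105,
                                     nac = 0.200, ila = 0.288),
                            time = c("0" = 0, "7" = -0.01, "14" = -0.02,
                                     "28" = -0.03, "70" = -0.04),
                            diet = c(SD = 0, HFD = 0.03)),
                          sd_mouse = 0.03, sd_area = 0.02, sd_slope = 0.02,
                          sd_resid = 0.03, rho_ar = 0.4,
                          parameter = "T2", seed = NULL) {
  if (any(c(sd_mouse, sd_area, sd_slope, sd_resid) < 0))
    stop("variance components must be >= 0")
  if (abs(rho_ar) >= 1) stop("|rho_ar| must be < 1")
  if (is.unsorted(days, strictly = TRUE)) stop("days must be strictly increasing")
  if (days[1] != 0) stop("days must include the baseline day 0")
  if (length(n_per_group) == 1) n_per_group <- stats::setNames(
    rep(n_per_group, length(diets)), diets)
  if (any(n_per_group < 2)) stop("n_per_group must be >= 2")
  structure(list(n_per_group = n_per_group, diets = diets, sexes = sexes,
                 days = days, regions = regions, beta = beta,
                 sd_mouse = sd_mouse, sd_area = sd_area, sd_slope = sd_slope,
                 sd_resid = sd_resid, rho_ar = rho_ar,
                 parameter = parameter, seed = seed),
            class = "mpmri_cohort_design")
}

eff1 <- function(v, name) if (is.null(v) || !name %in% names(v)) 0 else v[[name]]
eff2 <- function(m, n1, n2) {
  if (is.null(m)) return(0)
  if (!n1 %in% rownames(m) || !n2 %in% colnames(m)) return(0)
  m[n1, n2]
}
eff3 <- function(a, n1, n2, n3) {
  if (is.null(a)) return(0)
  dn <- dimnames(a)
  if (!n1 %in% dn[[1]] || !n2 %in% dn[[2]] || !n3 %in% dn[[3]]) return(0)
  a[n1, n2, n3]
}

#' Expected log response of a cohort design
#'
#' @param design an [cohort_design()] object.
#' @param diet,day,region vectors (recycled) of cell coordinates.
#' @return expected value of the log response in those cells (fixed
#'   effects only).
#' @export
cohort_expected_log <- function(design, diet, day, region) {
  b <- design$beta
  n <- max(length(diet), length(day), length(region))
  diet <- rep_len(as.character(diet), n)
  day <- rep_len(as.character(day), n)
  region <- rep_len(as.character(region), n)
  vapply(seq_len(n), function(i) {
    (b$intercept %||% 0) +
      eff1(b$area, region[i]) + eff1(b$time, day[i]) + eff1(b$diet, diet[i]) +
      eff2(b$area_time, region[i], day[i]) +
      eff2(b$diet_time, diet[i], day[i]) +
      eff2(b$diet_area, diet[i], region[i]) +
      eff3(b$diet_area_time, diet[i], region[i], day[i])
  }, numeric(1))
}

#' Simulate a longitudinal ROI table from a cohort design
#'
#' The log response of mouse i, region a, day t is
#' `mu(diet, t, a) + b_i + b_ia + s_i * t01 + e_iat`, with independent
#' Gaussian random effects (`b_i` mouse intercept, `b_ia` area-within-mouse
#' intercept, `s_i` slope on day rescaled to \[0, 1\]) and an AR(1)
#' residual over the time-point index within each mouse x area series.
#' The returned table is on the natural scale (exponentiated), one row
#' per mouse x day x region.
#'
#' @param design an [cohort_design()] object.
#' @param seed overrides `design$seed` when given.
#' @return long-format data frame: animal_id, sex, diet, day, region,
#'   parameter, value.
#' @examples
#' tab <- simulate_cohort(cohort_design(seed = 1))
#' nrow(tab)  # (7 + 8) mice x 2 sexes x 5 days x 4 regions
#' @export
simulate_cohort <- function(design, seed = NULL) {
  stopifnot(inherits(design, "mpmri_cohort_design"))
  seed <- seed %||% design$seed
  d <- design
  day01 <- d$days / max(d$days)
  nt <- length(d$days); na <- length(d$regions)

  with_seed(seed, {
    rows <- vector("list", 0L)
    id <- 0L
    for (sex in d$sexes) for (diet in d$diets) {
      for (m in seq_len(d$n_per_group[[diet]])) {
        id <- id + 1L
        aid <- sprintf("m%03d", id)
        b_m <- stats::rnorm(1, sd = d$sd_mouse)
        s_m <- stats::rnorm(1, sd = d$sd_slope)
        for (a in seq_len(na)) {
          b_ma <- stats::rnorm(1, sd = d$sd_area)
          # AR(1) residual over time-point index, stationary marginal sd
          z <- stats::rnorm(nt, sd = d$sd_resid)
          e <- numeric(nt)
          e[1] <- z[1]
          if (nt > 1) for (t in 2:nt)
            e[t] <- d$rho_ar * e[t - 1] + sqrt(1 - d$rho_ar^2) * z[t]
          mu <- cohort_expected_log(d, diet, d$days, d$regions[a])
          logy <- mu + b_m + b_ma + s_m * day01 + e
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = aid, sex = sex, diet = diet, day = d$days,
            region = d$regions[a], parameter = d$parameter,
            value = exp(logy), stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
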