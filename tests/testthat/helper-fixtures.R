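# shared fixtures and independent oracles

small_geometry <- function() list(matrix = 64L, fov_mm = 21, slice_thickness_mm = 1.25)

small_phantom <- function(truth = default_region_truth()) {
  make_phantom(truth = truth, geometry = small_geometry())
}

# protocol matching the small phantom geometry
small_protocol <- function(kind, overrides = list()) {
  make_protocol(kind, c(list(geometry = small_geometry()), overrides))
}

# brute-force dense grid search over the decay rate for y = S0 exp(-rate x),
# with the amplitude profiled out in closed form at each grid point;
# independent of the package's Levenberg-Marquardt path
oracle_grid_monoexp <- function(y, x, rate_grid) {
  sse <- vapply(rate_grid, function(r) {
    e <- exp(-r * x)
    s0 <- sum(y * e) / sum(e * e)
    sum((s0 * e - y)^2)
  }, numeric(1))
  r <- rate_grid[which.min(sse)]
  e <- exp(-r * x)
  list(rate = r, s0 = sum(y * e) / sum(e * e))
}

# Monte-Carlo familywise p for the max-|t| statistic of k contrasts
oracle_maxt_p <- function(t_obs, k, df, n_draws = 1e5, seed = 99) {
  mpmri:::with_seed(seed, {
    z <- matrix(rnorm(n_draws * k), n_draws, k)
    s <- sqrt(rchisq(n_draws, df) / df)
    tt <- abs(z / s)
    mx <- apply(tt, 1, max)
    vapply(abs(t_obs), function(ti) mean(mx >= ti), numeric(1))
  })
}

# quiet wrappers: nlme emits convergence chatter on degenerate fits
qfit <- function(...) suppressWarnings(fit_lme(...))
qselect <- function(...) suppressWarnings(select_best_model(...))
qanova <- function(...) suppressWarnings(anova_type3(...))

# cohort designs used across tests: area+time structure and pure null
at_design <- function(seed, n_per_group = c(SD = 7, HFD = 8)) {
  cohort_design(n_per_group = n_per_group, sexes = "male",
    beta = list(intercept = log(45),
      area = c(hypothalamus = 0, hippocampus = 0.105, nac = 0.2, ila = 0.288),
      time = c("0" = 0, "7" = -0.01, "14" = -0.02, "28" = -0.03, "70" = -0.04)),
    sd_slope = 0, seed = seed)
}

null_design <- function(seed, n_per_group = c(SD = 7, HFD = 8)) {
  cohort_design(n_per_group = n_per_group, sexes = "male",
    beta = list(intercept = log(45)), sd_slope = 0, seed = seed)
}

# reduced calibration design: more mice, fewer cells, no true diet effects
calib_design <- function(seed) {
  cohort_design(n_per_group = 12, sexes = "male", days = c(0, 7, 14),
    regions = c("hypothalamus", "hippocampus"),
    beta = list(intercept = log(45),
                area = c(hypothalamus = 0, hippocampus = 0.105)),
    sd_slope = 0, seed = seed)
}

# simulated metabolite ratio tables for the HRMAS mixed models
metabolite_table <- function(seed, n_per_diet = 14, interaction_sd = 0,
                             diet_effect = 0, resid_sd = 0.05) {
  mpmri:::with_seed(seed, {
    areas <- c("hypothalamus", "hippocampus", "nac", "ila")
    area_eff <- c(0, 0.1, -0.05, 0.05)
    rows <- list()
    id <- 0
    for (diet in c("SD", "HFD")) for (m in seq_len(n_per_diet)) {
      id <- id + 1
      b <- rnorm(1, sd = 0.05)
      for (a in seq_along(areas)) {
        inter <- if (diet == "HFD" && a %in% c(1, 2)) interaction_sd * resid_sd else 0
        rows[[length(rows) + 1]] <- data.frame(
          animal_id = sprintf("h%03d", id), diet = diet, area = areas[a],
          metabolite = "NAA",
          ratio_to_tcr = 1 + area_eff[a] + (diet == "HFD") * diet_effect +
            inter + b + rnorm(1, sd = resid_sd))
      }
    }
    do.call(rbind, rows)
  })
}
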