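test_that("single-component spectra are identified exactly", {
  bs <- make_basis_set()
  sp <- simulate_spectra(bs, c(NAA = 1))[[1]]
  fit <- fit_linear_combination(sp, bs)
  expect_equal(fit$amount[fit$metabolite == "NAA"], 1, tolerance = 1e-8)
  expect_lt(max(fit$amount[fit$metabolite != "NAA"]), 1e-8)
})

test_that("noise-free mixtures are recovered to numerical precision", {
  bs <- make_basis_set()
  truth <- c(NAA = 8, Cr = 4, PCr = 4, Lac = 2, mI = 5)
  sp <- simulate_spectra(bs, truth)[[1]]
  fit <- fit_linear_combination(sp, bs)
  got <- stats::setNames(fit$amount, fit$metabolite)
  expect_equal(got[names(truth)], truth, tolerance = 1e-6)
  expect_lt(max(got[setdiff(names(got), names(truth))]), 1e-6)
})

test_that("noisy mixtures are recovered within three standard errors", {
  bs <- make_basis_set()
  truth <- c(NAA = 8, Cr = 4, PCr = 4, Lac = 2, mI = 5)
  sp <- simulate_spectra(bs, truth, noise_sigma = 0.01 * 8 * max(bs$basis),
                         seed = 6)[[1]]
  fit <- fit_linear_combination(sp, bs)
  for (m in names(truth)) {
    row <- fit[fit$metabolite == m, ]
    expect_lt(abs(row$amount - truth[[m]]), 3 * row$SE + 1e-12)
  }
})

test_that("rank-deficient bases are rejected", {
  bs <- make_basis_set(n_points = 512)
  bs$basis[, "PCh"] <- bs$basis[, "Cho"]
  sp <- simulate_spectra(make_basis_set(n_points = 512), c(NAA = 1))[[1]]
  expect_error(fit_linear_combination(sp, bs), "collinear|deficient")
})

test_that("total-creatine ratios and composites follow their arithmetic", {
  amounts <- c(Cr = 4, PCr = 4, NAA = 8, Cho = 1, GPC = 0.5, PCh = 0.5,
               mI = 2, Gly = 1, Glu = 6, Gln = 2)
  r <- to_tcr_ratios(amounts)
  get <- function(m) r$ratio_to_tcr[r$metabolite == m]
  expect_equal(get("NAA"), 1)
  expect_equal(get("Cr+PCr"), 1)
  expect_equal(get("Cho+GPC+PCh"), get("Cho") + get("GPC") + get("PCh"))
  expect_equal(get("mI+Gly"), 0.375)
  expect_equal(get("Glu+Gln"), 1)
  expect_error(to_tcr_ratios(c(Cr = 0, PCr = 0, NAA = 1)), "positive")
  expect_error(to_tcr_ratios(c(NAA = 1)), "Cr")
})

test_that("ratios are invariant to global spectrum scaling", {
  bs <- make_basis_set()
  truth <- c(NAA = 8, Cr = 4, PCr = 4, mI = 5)
  sp <- simulate_spectra(bs, truth)[[1]]
  sp2 <- sp; sp2$intensity <- sp$intensity * 12.5
  r1 <- to_tcr_ratios(fit_linear_combination(sp, bs))
  r2 <- to_tcr_ratios(fit_linear_combination(sp2, bs))
  expect_equal(r2$ratio_to_tcr, r1$ratio_to_tcr, tolerance = 1e-8)
})

test_that("the round trip reproduces the generating ratio table", {
  bs <- make_basis_set()
  truth <- c(NAA = 8, Cr = 4.5, PCr = 3.5, Lac = 2, Tau = 3)
  sp <- simulate_spectra(bs, truth)[[1]]
  r <- to_tcr_ratios(fit_linear_combination(sp, bs))
  expect_equal(r$ratio_to_tcr[r$metabolite == "NAA"], 1, tolerance = 1e-6)
  expect_equal(r$ratio_to_tcr[r$metabolite == "Tau"], 3 / 8, tolerance = 1e-6)
})

test_that("the precision filter keeps the boundary and is idempotent", {
  tab <- data.frame(metabolite = c("a", "b", "c", "d"),
                    sd_percent = c(5, 20, 25, Inf))
  out <- filter_sd(tab)
  expect_equal(out$metabolite, c("a", "b"))
  expect_equal(filter_sd(out), out)
  empty <- filter_sd(tab[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("sd_percent shrinks with the noise level", {
  bs <- make_basis_set(n_points = 1024)
  truth <- c(NAA = 8, Cr = 4, PCr = 4)
  sds <- vapply(c(hi = 0.02, lo = 0.002), function(sig) {
    mean(vapply(1:20, function(i) {
      sp <- simulate_spectra(bs, truth, noise_sigma = sig * max(bs$basis) * 8,
                             seed = 500 + i)[[1]]
      fit <- fit_linear_combination(sp, bs)
      fit$sd_percent[fit$metabolite == "NAA"]
    }, numeric(1)))
  }, numeric(1))
  expect_lt(sds[["lo"]], sds[["hi"]])
})

test_that("the interaction model is chosen when a strong diet:area effect exists", {
  hits <- vapply(1:50, function(i) {
    tab <- metabolite_table(3000 + i, interaction_sd = 2)
    metabolite_model_compare(tab, "NAA")$chosen == "diet+area+diet:area"
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("null metabolite data rarely shows a diet effect", {
  ps <- vapply(1:50, function(i) {
    m <- metabolite_model_compare(metabolite_table(4000 + i), "NAA")
    metabolite_tests(m)$anova$p[1]   # diet term
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("metabolite tests report the Table-2 style schema", {
  tab <- metabolite_table(777, interaction_sd = 3)
  m <- metabolite_model_compare(tab, "NAA")
  tt <- metabolite_tests(m)
  expect_setequal(tt$anova$term, c("diet", "area", "diet:area"))
  # single-df Wald identity for the diet term
  est <- nlme::fixef(m$fit)[["diet1"]]
  se <- sqrt(stats::vcov(m$fit)["diet1", "diet1"])
  expect_equal(tt$anova$chisq[tt$anova$term == "diet"], (est / se)^2,
               tolerance = 1e-8)
  expect_equal(nrow(tt$posthoc), 4)   # one diet contrast per area
  expect_true(all(tt$posthoc$p_adjusted >= tt$posthoc$p_raw - 1e-12))
  expect_error(metabolite_model_compare(tab[tab$diet == "SD", ], "NAA"), "2 diets")
})
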