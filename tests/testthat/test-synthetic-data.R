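test_that("phantom regions carry exact counts and CSF truth violates the filters", {
  ph <- make_phantom()
  codes <- ph$region_codes
  expect_equal(sum(ph$label == codes[["hypothalamus"]]), 70)
  expect_equal(sum(ph$label == codes[["hippocampus"]]), 60)
  expect_equal(sum(ph$label == codes[["nac"]]), 80)
  expect_equal(sum(ph$label == codes[["ila"]]), 20)
  expect_true(sum(ph$label == codes[["csf"]]) > 0)
  csf <- ph$truth[ph$truth$region == "csf", ]
  expect_gt(csf$T2_ms, 80)
  expect_gt(csf$ADC_um2s, 1200)
  expect_lte(csf$MTR_percent, 0)
})

test_that("phantom construction validates its inputs", {
  expect_error(make_phantom(geometry = list(matrix = 0)), "positive")
  truth <- default_region_truth()
  expect_error(make_phantom(truth = truth[truth$region != "csf", ]), "missing")
  bad <- truth; bad$T2_ms[1] <- -1
  expect_error(make_phantom(truth = bad), "T2")
})

test_that("noiseless series equal the closed-form signals", {
  ph <- small_phantom()
  codes <- ph$region_codes
  vox <- which(ph$label == codes[["hypothalamus"]])[1]

  t2p <- small_protocol("t2map", list(n_echoes = 8))
  st <- simulate_series(ph, t2p, 0, "none")
  sig <- vapply(seq_len(8), function(k) st$data[row(ph$label)[vox], col(ph$label)[vox], k],
                numeric(1))
  expect_equal(sig, 1000 * exp(-t2p$te_ms / 45), tolerance = 1e-12)

  dp <- small_protocol("dwi_female")
  sd_ <- simulate_series(ph, dp, 0, "none")
  sigd <- sd_$data[row(ph$label)[vox], col(ph$label)[vox], ]
  expect_equal(sigd, 1000 * exp(-dp$b_values * 700e-6), tolerance = 1e-12)

  mp <- small_protocol("mt_pair")
  sm <- simulate_series(ph, mp, 0, "none")
  expect_equal(sm$data[row(ph$label)[vox], col(ph$label)[vox], 2] /
               sm$data[row(ph$label)[vox], col(ph$label)[vox], 1],
               1 - 35 / 100, tolerance = 1e-12)
})

test_that("simulators are bit-identical under a fixed seed", {
  ph <- small_phantom()
  p <- small_protocol("t2map", list(n_echoes = 5))
  a <- simulate_series(ph, p, 10, "rician", seed = 7)
  b <- simulate_series(ph, p, 10, "rician", seed = 7)
  c_ <- simulate_series(ph, p, 10, "rician", seed = 8)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c_$data))

  d <- cohort_design(seed = 5)
  expect_identical(simulate_cohort(d), simulate_cohort(d))

  bs <- make_basis_set(n_points = 256)
  s1 <- simulate_spectra(bs, c(NAA = 1), noise_sigma = 0.1, seed = 3)
  s2 <- simulate_spectra(bs, c(NAA = 1), noise_sigma = 0.1, seed = 3)
  expect_identical(s1[[1]]$intensity, s2[[1]]$intensity)
})

test_that("Rician noise has the Rayleigh mean at zero signal and vanishing bias at high SNR", {
  mpmri:::with_seed(11, {
    draws <- add_acquisition_noise(array(0, c(100, 100)), 10, "rician")
    se <- sqrt((2 - pi / 2) * 100 / 1e4)
    expect_lt(abs(mean(draws) - 10 * sqrt(pi / 2)), 3 * se)
    # SNR 50: mean bias of the magnitude signal ~ sigma/(2 SNR)
    s <- 500; sigma <- 10
    hi <- add_acquisition_noise(array(s, c(100, 100)), sigma, "rician")
    bias <- mean(hi) - s
    expect_lt(abs(bias), sigma * (1 / (2 * 50) + 3 / 100))
  })
})

test_that("zero-variance cohorts reproduce exp(X beta) exactly", {
  d <- cohort_design(sd_mouse = 0, sd_area = 0, sd_slope = 0, sd_resid = 0,
                     rho_ar = 0, seed = 1)
  tab <- simulate_cohort(d)
  mu <- cohort_expected_log(d, tab$diet, tab$day, tab$region)
  expect_equal(log(tab$value), mu, tolerance = 1e-12)
})

test_that("default cohort design has the study layout", {
  tab <- simulate_cohort(cohort_design(seed = 2))
  expect_setequal(unique(tab$day), c(0, 7, 14, 28, 70))
  expect_setequal(unique(tab$diet), c("SD", "HFD"))
  expect_length(unique(tab$region), 4)
  one <- tab[tab$animal_id == tab$animal_id[1], ]
  expect_equal(nrow(one), 20)  # 5 time points x 4 regions
  # 7 SD + 8 HFD per sex
  counts <- table(unique(tab[c("animal_id", "diet")])$diet)
  expect_equal(as.vector(counts[c("SD", "HFD")]), c(14, 16))
})

test_that("AR(1) residuals show the generating lag-1 autocorrelation", {
  d <- cohort_design(n_per_group = 250, sexes = "male", sd_mouse = 0,
                     sd_area = 0, sd_slope = 0, sd_resid = 0.05,
                     rho_ar = 0.6, seed = 5)
  tab <- simulate_cohort(d)
  mu <- cohort_expected_log(d, tab$diet, tab$day, tab$region)
  e <- matrix(log(tab$value) - mu, nrow = 5)  # columns are mouse x area series
  acf1 <- cor(as.vector(e[-5, ]), as.vector(e[-1, ]))
  expect_lt(abs(acf1 - 0.6), 0.05)
})

test_that("marginal log-scale variance is the sum of the components", {
  d <- cohort_design(n_per_group = 400, sexes = "male", days = c(0, 7),
                     regions = c("hypothalamus", "hippocampus"),
                     beta = list(intercept = 0),
                     sd_mouse = 0.04, sd_area = 0.03, sd_slope = 0,
                     sd_resid = 0.05, rho_ar = 0.5, seed = 9)
  tab <- simulate_cohort(d)
  v <- stats::var(log(tab$value[tab$day == 0]))
  expect_lt(abs(v - (0.04^2 + 0.03^2 + 0.05^2)) / (0.04^2 + 0.03^2 + 0.05^2), 0.15)
})

test_that("cohort design rejects invalid settings", {
  expect_error(cohort_design(rho_ar = 1), "rho")
  expect_error(cohort_design(sd_mouse = -1), "variance")
  expect_error(cohort_design(n_per_group = 1), ">= 2")
  expect_error(cohort_design(days = c(0, 14, 7)), "increasing")
  expect_error(cohort_design(days = c(7, 14)), "day 0")
})

test_that("single-component spectra equal the scaled basis column", {
  bs <- make_basis_set(n_points = 512)
  sp <- simulate_spectra(bs, c(NAA = 2.5))[[1]]
  expect_equal(sp$intensity, 2.5 * bs$basis[, "NAA"], tolerance = 1e-12)
  expect_error(simulate_spectra(bs, c(Unobtainium = 1)), "unknown")
  expect_error(simulate_spectra(bs, c(NAA = -1)), ">= 0")
})
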