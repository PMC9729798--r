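test_that("default template realises the printed voxel counts, disjointly", {
  m <- make_roi_masks(roi_template(), list(matrix = 128))
  codes <- attr(m, "region_codes")
  expect_equal(sum(m == codes[["hypothalamus"]]), 70)
  expect_equal(sum(m == codes[["hippocampus"]]), 60)   # two squares of 30
  expect_equal(sum(m == codes[["nac"]]), 80)           # two ovals of 40
  expect_equal(sum(m == codes[["ila"]]), 20)
  # disjoint by construction: labels partition the labelled voxels
  expect_equal(sum(m > 0), 70 + 60 + 80 + 20)
  expect_error(make_roi_masks(roi_template(), list(matrix = 16)), "too small")
})

test_that("value filters apply the strict printed bounds", {
  t2 <- filter_map_values(c(25, 45, 85), "T2")
  expect_equal(t2$values, 45)
  expect_equal(t2$n_removed, 2L)
  adc <- filter_map_values(c(-50, 600, 1300), "ADC")
  expect_equal(adc$values, 600)
  mtr <- filter_map_values(c(-10, 0, 5), "MTR")
  expect_equal(mtr$values, 5)
  # boundaries are excluded
  expect_length(filter_map_values(c(30, 80), "T2")$values, 0)
  expect_length(filter_map_values(c(0, 1200), "ADC")$values, 0)
  expect_warning(out <- filter_map_values(numeric(0), "T2"), "empty")
  expect_length(out$values, 0)
  # idempotence
  once <- filter_map_values(c(25, 45, 85), "T2")$values
  expect_equal(filter_map_values(once, "T2")$values, once)
})

test_that("roi_mean averages valid, filter-passing voxels only", {
  vals <- matrix(45, 10, 10)
  map <- param_map("T2", vals, valid = matrix(TRUE, 10, 10))
  mask <- matrix(FALSE, 10, 10); mask[1:7, 1:10] <- TRUE
  r <- roi_mean(map, mask)
  expect_equal(r$value, 45)
  expect_equal(r$n_voxels_used, 70)

  # CSF-like voxels (T2 = 150) inside the mask are excluded by the filter
  vals2 <- vals; vals2[1, ] <- 150
  map2 <- param_map("T2", vals2, valid = matrix(TRUE, 10, 10))
  r2 <- roi_mean(map2, mask)
  expect_equal(r2$value, 45)
  expect_equal(r2$n_voxels_used, 60)

  # all voxels invalid -> missing value with a reason
  map3 <- param_map("T2", vals, valid = matrix(FALSE, 10, 10))
  r3 <- roi_mean(map3, mask)
  expect_true(is.na(r3$value))
  expect_equal(r3$n_voxels_used, 0L)
  expect_false(is.na(r3$reason))
})

test_that("roi_mean is invariant to mask relabelling", {
  vals <- matrix(rnorm(100, 50, 2), 10, 10)
  map <- param_map("T2", vals, valid = matrix(TRUE, 10, 10))
  lab <- matrix(0L, 10, 10); lab[3:5, 3:5] <- 7L
  lab2 <- lab; lab2[lab == 7L] <- 42L
  expect_equal(roi_mean(map, lab, label = 7L), roi_mean(map, lab2, label = 42L))
})

test_that("IQR outlier rule matches the hand-worked example", {
  out <- remove_outliers_iqr(c(10, 11, 12, 13, 100))
  expect_equal(as.vector(out), c(10, 11, 12, 13))
  expect_equal(attr(out, "removed"), 100)
  # fences under the linear-interpolation quartile convention
  expect_equal(unname(stats::quantile(c(10, 11, 12, 13, 100), c(.25, .75))),
               c(11, 13))
  # all equal: IQR 0, fences at the common value, nothing removed
  expect_length(remove_outliers_iqr(rep(5, 6)), 6)
  # groups below 4 skip removal
  tiny <- remove_outliers_iqr(c(1, 2, 1000))
  expect_length(tiny, 3)
  expect_equal(attr(tiny, "skipped_groups"), "n < 4")
  # idempotent on its own output
  once <- remove_outliers_iqr(c(10, 11, 12, 13, 100))
  twice <- remove_outliers_iqr(as.vector(once))
  expect_equal(as.vector(twice), as.vector(once))
})

test_that("grouped outlier removal respects diet x day x region cells", {
  df <- data.frame(
    diet = rep(c("SD", "HFD"), each = 5),
    day = 0, region = "hypothalamus",
    value = c(10, 11, 12, 13, 100, 20, 21, 22, 23, 24))
  out <- remove_outliers_iqr(df)
  expect_equal(nrow(out), 9)
  expect_equal(attr(out, "removed")$value, 100)
})

test_that("build_roi_table aggregates one row per key and applies the rules", {
  masks <- make_roi_masks(roi_template(), list(matrix = 128))
  mk_map <- function(v) param_map("T2", matrix(v, 128, 128),
                                  valid = matrix(TRUE, 128, 128))
  records <- list()
  for (an in c("m1", "m2")) for (day in c(0, 7)) {
    records[[length(records) + 1]] <- list(
      animal_id = an, sex = "male", diet = "SD", day = day,
      maps = list(T2 = mk_map(45)))
  }
  tab <- build_roi_table(records, masks)
  expect_equal(nrow(tab), 16)  # 2 animals x 2 days x 4 regions
  expect_true(all(tab$value == 45))

  dup <- c(records, records[1])
  expect_error(build_roi_table(dup, masks), "duplicate")
})

test_that("an aberrant animal mean is dropped by the IQR rule", {
  masks <- make_roi_masks(roi_template(), list(matrix = 128))
  mk_map <- function(v) param_map("T2", matrix(v, 128, 128),
                                  valid = matrix(TRUE, 128, 128))
  vals <- c(44, 45, 45.5, 46, 79)   # last animal aberrant but filter-passing
  records <- lapply(seq_along(vals), function(i) list(
    animal_id = paste0("m", i), sex = "male", diet = "SD", day = 0,
    maps = list(T2 = mk_map(vals[i]))))
  tab <- build_roi_table(records, masks)
  expect_false(any(tab$animal_id == "m5"))
  expect_equal(nrow(tab), 16)       # 4 animals x 4 regions
  expect_equal(sort(unique(attr(tab, "removed")$animal_id)), "m5")
})

test_that("ROI tables round-trip through CSV unchanged", {
  tab <- simulate_cohort(cohort_design(seed = 3))
  f <- tempfile(fileext = ".csv")
  write_roi_table(tab, f)
  back <- read_roi_table(f)
  expect_equal(back$value, tab$value, tolerance = 1e-12)
  expect_identical(back$animal_id, tab$animal_id)
  expect_identical(back$region, tab$region)
  unlink(f)
})
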