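test_that("count datasets validate and round-trip through text files", {
  y <- matrix(c(1L, 0L, 2L, 2L), 2, 2, byrow = TRUE)
  d <- nest_counts(y, plot_ids = c("A", "B"),
                   survey_covariates = list(wind = matrix(1:4, 2, 2)),
                   plot_covariates = data.frame(biomass = c(900, 1400)))
  expect_identical(unname(d$y), y)
  expect_true(all(d$observed_mask))

  tmp1 <- tempfile(fileext = ".csv"); tmp2 <- tempfile(fileext = ".csv")
  write_nest_counts(d, tmp1, tmp2)
  d2 <- read_nest_counts(tmp1, tmp2)
  expect_identical(unname(d2$y), unname(d$y))
  expect_identical(unname(d2$observed_mask), unname(d$observed_mask))
  expect_equal(unname(d2$survey_covariates$wind),
               unname(d$survey_covariates$wind))
  expect_equal(d2$plot_covariates$biomass, d$plot_covariates$biomass)
})

test_that("unsurveyed occasions are masked, never imputed", {
  long <- data.frame(plot_id = c("A", "A", "A", "B", "B"),
                     occasion = c(1, 2, 3, 1, 2),
                     count = c(1, 0, 2, 3, 1))
  tmp <- tempfile(fileext = ".csv")
  write.csv(long, tmp, row.names = FALSE)
  d <- read_nest_counts(tmp)
  expect_false(d$observed_mask[2, 3])
  expect_true(is.na(d$y[2, 3]))
  expect_true(all(d$observed_mask[1, ]))
})

test_that("invalid counts are rejected", {
  long <- data.frame(plot_id = "A", occasion = 1, count = -1)
  tmp <- tempfile(fileext = ".csv")
  write.csv(long, tmp, row.names = FALSE)
  expect_error(read_nest_counts(tmp), "negative")
  expect_error(nest_counts(matrix(c(0.5, 1, 1, 1), 2, 2)), "integer")
  long2 <- data.frame(plot_id = c("A", "A"), occasion = c(1, 1),
                      count = c(1, 2))
  write.csv(long2, tmp, row.names = FALSE)
  expect_error(read_nest_counts(tmp), "duplicate")
})

test_that("encounter records enforce interval and fate invariants", {
  expect_s3_class(toy_records(), "nest_records")
  bad <- data.frame(nest_id = "n", plot_id = "A", first_found = 5,
                    last_active = 4, last_checked = 6, fate = "failure")
  expect_error(nest_records(bad), "first_found")
  bad$last_active <- 6; bad$fate <- "success"; bad$last_checked <- 9
  expect_error(nest_records(bad), "success")
  bad$fate <- "failure"; bad$last_checked <- 6
  expect_error(nest_records(bad), "window")
})

test_that("encounter-history export is the documented plain format", {
  tmp <- tempfile()
  write_encounter_histories(toy_records(), tmp)
  lines <- readLines(tmp)
  expect_identical(lines[1], "5 15 15 1")
  expect_identical(lines[2], "3 9 12 0")
})

test_that("cover bins map to midpoints and reject unknown labels", {
  expect_equal(cover_bin_midpoint("0-5"), 0.025)
  expect_equal(cover_bin_midpoint("96-100"), 0.98)
  expect_equal(cover_bin_midpoint(c("6-25", "26-50", "51-75", "76-95")),
               c(0.155, 0.38, 0.63, 0.855))
  expect_equal(cover_bin_midpoint("0–5"), 0.025)  # en dash accepted
  expect_error(cover_bin_midpoint("40-60"), "unknown cover bin")
})

test_that("biomass calibration applies observer and drying offsets", {
  # observer X overestimates green weight by 1 g on average; drying
  # removes 3 g on average
  green_calib <- data.frame(observer_id = "X",
                            estimated_green = c(12, 8),
                            clipped_green = c(10, 8))
  dry_calib <- data.frame(clipped_green = c(10, 10), dry = c(6, 8))
  out <- calibrate_biomass(11, "X", green_calib, dry_calib)
  expect_equal(out$green_g, 10)
  expect_equal(out$dry_g, 7)
  expect_equal(out$dry_kg_ha, 700)  # 0.1 m2 frame

  # zero-offset calibration is the identity
  gc0 <- data.frame(observer_id = "Z", estimated_green = c(5, 7),
                    clipped_green = c(5, 7))
  dc0 <- data.frame(clipped_green = c(5, 7), dry = c(5, 7))
  out0 <- calibrate_biomass(c(3, 9), c("Z", "Z"), gc0, dc0)
  expect_equal(out0$dry_g, c(3, 9))

  # corrections cannot push mass below zero
  gcn <- data.frame(observer_id = "W", estimated_green = 10,
                    clipped_green = 6)
  out_n <- calibrate_biomass(1, "W", gcn, dry_calib)
  expect_equal(out_n$green_g, 0)
  expect_equal(out_n$dry_g, 0)

  expect_error(calibrate_biomass(1, "unknown", green_calib, dry_calib),
               "absent")
})

test_that("standardization centres and scales with the sample SD", {
  std <- standardize_covariates(data.frame(x = c(1, 2, 3)))
  expect_equal(std$data$x, c(-1, 0, 1))
  expect_equal(unname(std$center["x"]), 2)
  expect_equal(unname(std$scale["x"]), 1)

  # idempotent up to floating error on already-standardized input
  std2 <- standardize_covariates(std$data)
  expect_equal(std2$data$x, std$data$x, tolerance = 1e-12)

  expect_error(standardize_covariates(data.frame(x = c(5, 5, 5))),
               "constant")
})

test_that("standardize and unstandardize are mutually inverse", {
  set.seed(11)
  df <- data.frame(a = rnorm(20, 100, 15), b = runif(20))
  std <- standardize_covariates(df)
  back <- unstandardize_covariates(std)
  expect_equal(back$a, df$a, tolerance = 1e-12)
  expect_equal(back$b, df$b, tolerance = 1e-12)
  # coefficient mapping: slope per SD / SD = slope per unit
  expect_equal(real_scale_coef(1.5, std$scale[["a"]]),
               1.5 / sd(df$a))
  expect_equal(real_scale_coef(0.8, 2, degree = 2), 0.2)
})
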