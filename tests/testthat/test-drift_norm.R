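test_that("boxplot fences flag exactly the textbook outliers", {
  expect_equal(boxplot_outlier_mask(rep(5, 10)), rep(FALSE, 10))
  x <- c(10, 11, 11, 12, 12, 13, 100)
  expect_equal(boxplot_outlier_mask(x), x == 100)
  y <- c(-50, 10, 11, 12, 13)
  expect_equal(boxplot_outlier_mask(y), y == -50)
  expect_warning(m <- boxplot_outlier_mask(c(1, 2, 3)), "fewer than 4")
  expect_equal(m, rep(FALSE, 3))
  # missing values are never flagged and do not disturb the fences
  z <- c(10, 11, NA, 12, 13, 100)
  expect_equal(boxplot_outlier_mask(z), !is.na(z) & z == 100)
})

test_that("drift trend equals windowed means, with sane degenerate behaviour", {
  # constants stay constant under any mask
  expect_equal(fit_drift_trend(1:50, rep(7, 50), 20), rep(7, 50))
  # linear values: interior trend is the window mean (brute-force check)
  acq <- 1:100
  v <- as.numeric(acq)
  tr <- fit_drift_trend(acq, v, 10)
  expect_equal(tr, oracle_trend(acq, v, 10, rep(TRUE, 100)), tolerance = 1e-12)
  expect_equal(tr[50], mean(40:60))
  # isolated samples see only themselves
  acq2 <- c(0, 100, 200)
  expect_equal(fit_drift_trend(acq2, c(5, 9, 13), 20), c(5, 9, 13))
  # positions with no included neighbour inherit the nearest defined trend
  inc <- rep(TRUE, 3); inc[3] <- FALSE
  expect_message(
    tr2 <- fit_drift_trend(c(0, 10, 500), c(4, 6, 100), 20, inc),
    "nearest")
  expect_equal(tr2, c(5, 5, 5))
  expect_error(fit_drift_trend(1:5, rep(NA_real_, 5), 10), "no included")
  expect_error(fit_drift_trend(1:5, 1:5, 0), "radius")
})

test_that("ratio correction rescales to the screen median and clips", {
  expect_equal(correct_concentrations(50, 50, screen_median = 80), 80)
  expect_equal(correct_concentrations(100, 50, screen_median = 50), 100)
  expect_equal(correct_concentrations(0, 120, screen_median = 50, clip = 0.01),
               0.01)
  expect_equal(correct_concentrations(c(NA, 60), c(30, 30), 40), c(NA, 80))
  expect_error(correct_concentrations(5, -1, 40), "position")
  expect_error(correct_concentrations(5, 1, 0), "screen_median")
})

test_that("correction removes an imposed drift from a single batch", {
  withr::local_seed(17)
  n <- 300
  drift <- drift_profile(n, 0.2, seed = 99)
  base <- 100
  v <- base * drift * exp(rnorm(n, 0, 0.09))
  tbl <- tibble::tibble(
    batch_id = "b1", acquisition_index = 1:n, plate_id = "p1",
    well = NA_character_, role = "experimental", species = "s",
    replicate = 1L, compound_id = sprintf("c%03d", 1:n), metabolite = "m",
    raw_conc_uM = v)
  out <- normalise_screen(tbl, screen_config())
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(out$corrected_conc_uM), cv(out$raw_conc_uM))
  # corrected values are centred on the screen median of the raw data
  expect_equal(median(out$corrected_conc_uM), median(v), tolerance = 0.02)
})

test_that("correction is idempotent up to the global rescale on flat data", {
  tbl <- tibble::tibble(
    batch_id = "b1", acquisition_index = 1:80, plate_id = "p1",
    well = NA_character_, role = "experimental", species = "s",
    replicate = 1L, compound_id = sprintf("c%03d", 1:80), metabolite = "m",
    raw_conc_uM = rep(c(90, 110), 40))
  out <- normalise_screen(tbl, screen_config(trend_radius = 100))
  # every window covers the whole flat batch: trend = 100 everywhere and the
  # correction reduces to the global rescale raw / 100 * median(raw)
  expect_equal(out$trend_value, rep(100, 80), tolerance = 1e-12)
  expect_equal(out$corrected_conc_uM, tbl$raw_conc_uM / 100 * median(tbl$raw_conc_uM),
               tolerance = 1e-12)
})

test_that("row order of the input does not change corrected values", {
  sim <- generate_screen(small_scenario(rng_seed = 12))
  m <- sim$measurements
  cfg <- screen_config()
  out1 <- normalise_screen(m, cfg)
  perm <- withr::with_seed(1, sample(nrow(m)))
  out2 <- normalise_screen(m[perm, ], cfg)
  out2_orig <- out2[order(perm), ]
  expect_equal(out2_orig$corrected_conc_uM, out1$corrected_conc_uM,
               tolerance = 1e-12)
})

test_that("standards, blanks and QC injections never shape the trend", {
  # a huge standard next to samples must not move their trend values
  tbl <- tibble::tibble(
    batch_id = "b1", acquisition_index = 1:41, plate_id = "p1",
    well = NA_character_,
    role = c(rep("experimental", 20), "standard", rep("experimental", 20)),
    species = "s", replicate = 1L,
    compound_id = c(sprintf("c%02d", 1:20), NA, sprintf("d%02d", 1:20)),
    metabolite = "m",
    raw_conc_uM = c(rep(100, 20), 1e6, rep(100, 20)))
  out <- normalise_screen(tbl, screen_config())
  expect_equal(out$trend_value[out$role == "experimental"], rep(100, 40))
})
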