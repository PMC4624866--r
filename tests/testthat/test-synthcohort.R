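bands <- standard_bands()

test_that("planted band signal is spectrally pure with exact sample SD", {
  sig <- plant_band_signal(230, 2, bands[["slow-4"]], 1.0, seed = 7)
  expect_equal(sd(sig), 1.0, tolerance = 1e-9)
  expect_equal(mean(sig), 0, tolerance = 1e-12)
  sp <- amplitude_spectrum(sig, 2)
  outside <- !band_bin_mask(sp$frequencies, bands[["slow-4"]])
  expect_lt(max(sp$amplitudes[outside]), 1e-12)

  expect_equal(plant_band_signal(230, 2, bands[["slow-4"]], 0, seed = 1),
               rep(0, 230))
  expect_error(plant_band_signal(230, 2, frequency_band("hi", 0.3, 0.4),
                                 1, 1), "invalid band")
  expect_error(plant_band_signal(230, 2, bands[["slow-4"]], -1, 1),
               "target_sd")
})

test_that("plant_covariate hits its target correlation", {
  set.seed(12)
  x <- rnorm(39)
  expect_equal(cor(x, plant_covariate(x, 1.0, 5)), 1.0, tolerance = 1e-12)

  # independence at r = 0: |r| below the 4/sqrt(n) sampling bound
  x0 <- rnorm(400)
  expect_lt(abs(cor(x0, plant_covariate(x0, 0, 6))), 4 / sqrt(400))

  # Monte Carlo over seeds at n = 39: mean sample r within 0.5 +/- 0.03
  rs <- vapply(1:500, function(s) cor(x, plant_covariate(x, 0.5, s)),
               numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.03)

  expect_error(plant_covariate(rep(1, 10), 0.5, 1), "constant")
  expect_error(plant_covariate(rnorm(10), 1.5, 1), "target_r")
})

test_that("cohort generation is deterministic and respects group sizes", {
  spec <- synthetic_spec(4, 5, grid_dims = c(6, 6, 5), n_timepoints = 40,
                         seed = 31, roi_list = list(
                           roi_box("r", c(2, 2, 2), c(3, 3, 3),
                                   bands[["slow-4"]])))
  co1 <- generate_cohort(spec, keep_runs = TRUE)
  co2 <- generate_cohort(spec, keep_runs = TRUE)
  expect_equal(nrow(co1$pheno), 9)
  expect_equal(sum(co1$pheno$group == 1), 4)
  expect_identical(serialize(co1, NULL), serialize(co2, NULL))
})

test_that("outlier designation follows round(fraction * n) per group", {
  spec <- synthetic_spec(5, 3, grid_dims = c(5, 5, 4), n_timepoints = 40,
                         motion_outlier_fraction = 0.25, seed = 3)
  co <- generate_cohort(spec)
  tab <- table(co$pheno$group, co$pheno$motion_outlier)
  expect_equal(unname(tab["1", "TRUE"]), round(0.25 * 5))
  expect_equal(unname(tab["2", "TRUE"]), round(0.25 * 3))
})

test_that("noiseless runs: non-ROI voxels are constant, ROI band-ALFF ratio equals the multiplier ratio", {
  spec <- tiny_spec(noise_sd = 0, drift_slope_sd = 0, amplitude_jitter_sd = 0,
                    roi_list = list(tiny_roi(g1 = 1.5, g2 = 1.0)))
  r1 <- generate_subject_run(spec, 1L, 101L)$run
  r2 <- generate_subject_run(spec, 2L, 102L)$run
  expect_equal(sd(r1$data[9, 9, 7, ]), 0)          # non-ROI voxel constant
  expect_equal(r1$data[9, 9, 7, 1], 100)           # baseline only

  mask <- cohort_mask(spec)
  b4 <- list(bands[["slow-4"]])
  a1 <- compute_band_maps(preprocess_run(r1, fwhm_mm = 0), mask, b4)[[1]]$alff
  a2 <- compute_band_maps(preprocess_run(r2, fwhm_mm = 0), mask, b4)[[1]]$alff
  roi <- array(FALSE, tiny_grid); roi[3:6, 3:6, 3:5] <- TRUE
  expect_true(all(a1[roi] > 0) && all(a2[roi] > 0))
  # ALFF linearity oracle: scaling a run's planted signal by 1.5 must scale
  # its ROI band-ALFF by exactly 1.5 (the multiplier acts the same way)
  r2s <- r2; r2s$data <- (r2s$data - 100) * 1.5 + 100
  a2s <- compute_band_maps(preprocess_run(r2s, fwhm_mm = 0), mask, b4)[[1]]$alff
  expect_equal(a2s[roi] / a2[roi], rep(1.5, sum(roi)), tolerance = 1e-6)

  expect_error(generate_subject_run(spec, 3L, 1L), "group")
})

test_that("increasing the group-1 multiplier increases group-1 ROI ALFF only", {
  mk <- function(mult) {
    spec <- tiny_spec(noise_sd = 0, drift_slope_sd = 0, amplitude_jitter_sd = 0,
                      roi_list = list(tiny_roi(g1 = mult, g2 = 1.0)))
    run <- preprocess_run(generate_subject_run(spec, 1L, 55L)$run, fwhm_mm = 0)
    compute_band_maps(run, cohort_mask(spec), list(bands[["slow-4"]]))[[1]]$alff
  }
  lo <- mk(1.0); hi <- mk(1.3)
  roi <- array(FALSE, tiny_grid); roi[3:6, 3:6, 3:5] <- TRUE
  expect_true(all(hi[roi] > lo[roi]))
  expect_equal(hi[!roi], lo[!roi])
})

test_that("coupled covariates carry the planted correlation with ROI amplitude", {
  spec <- synthetic_spec(30, 2, grid_dims = c(5, 5, 4), n_timepoints = 40,
                         seed = 77,
                         roi_list = list(roi_box("r", c(2, 2, 2), c(3, 3, 3),
                                                 bands[["slow-4"]])),
                         covariate_couplings = list(
                           coupling_spec("thq", "r", 0.9)))
  co <- generate_cohort(spec)
  g1 <- co$pheno$group == 1
  r <- cor(co$amplitudes[g1, "r"], co$pheno$thq[g1])
  expect_gt(r, 0.6)   # 0.9 planted, minus clipping/rounding attenuation
  expect_true(all(is.na(co$pheno$thq[!g1])))
})
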