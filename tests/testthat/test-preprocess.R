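test_that("detrend_linear removes exact lines and is idempotent", {
  n <- 50
  expect_equal(detrend_linear(5 + 0.3 * seq_len(n)), rep(0, n),
               tolerance = 1e-12)
  expect_equal(detrend_linear(rep(4.2, n)), rep(0, n), tolerance = 1e-12)

  # a line-orthogonalized sinusoid rides through the fit untouched,
  # and the general case matches the lm() residual oracle
  tr <- 2
  tm <- seq_len(n)
  s <- sin(2 * pi * (8 / (n * tr)) * (0:(n - 1)) * tr)
  s_perp <- unname(resid(lm(s ~ tm)))
  x <- 2 - 0.7 * tm + s_perp
  expect_equal(detrend_linear(x), s_perp, tolerance = 1e-10)
  set.seed(30)
  z <- rnorm(n) + 0.2 * tm
  expect_equal(detrend_linear(z), unname(resid(lm(z ~ tm))),
               tolerance = 1e-10)

  set.seed(1)
  y <- rnorm(40)
  expect_equal(detrend_linear(detrend_linear(y)), detrend_linear(y),
               tolerance = 1e-12)
  expect_error(detrend_linear(c(1, 2)), "3 timepoints")
})

test_that("detrend_linear matrix form matches column-by-column application", {
  set.seed(2)
  m <- matrix(rnorm(30 * 5), 30, 5)
  ref <- apply(m, 2, detrend_linear)
  expect_equal(detrend_linear(m), ref, tolerance = 1e-12)
})

test_that("Gaussian smoothing: impulse response matches the kernel formula", {
  v <- array(0, c(21, 21, 21)); v[11, 11, 11] <- 1
  sm <- smooth_gaussian(v, fwhm_mm = 6, voxel_size_mm = 3)
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3
  r <- ceiling(4 * sigma)
  w <- exp(-(-r:r)^2 / (2 * sigma^2)); w <- w / sum(w)
  expect_equal(sm[11, 11, 11], w[r + 1]^3, tolerance = 1e-12)
  expect_equal(sm[12, 11, 11], w[r + 2] * w[r + 1]^2, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-8)   # interior mass conservation
})

test_that("smoothing is identity at fwhm 0, preserves uniform fields, commutes with constants", {
  set.seed(4)
  x <- array(rnorm(8 * 7 * 6), c(8, 7, 6))
  expect_identical(smooth_gaussian(x, 0, 3), x)
  expect_equal(smooth_gaussian(array(5, c(6, 6, 6)), 6, 3),
               array(5, c(6, 6, 6)), tolerance = 1e-12)
  expect_equal(smooth_gaussian(x + 3, 6, 3), smooth_gaussian(x, 6, 3) + 3,
               tolerance = 1e-10)
  expect_error(smooth_gaussian(x, -1, 3), "fwhm")
})

test_that("4D smoothing equals per-volume 3D smoothing", {
  set.seed(5)
  x <- array(rnorm(6 * 6 * 5 * 3), c(6, 6, 5, 3))
  sm <- smooth_gaussian(x, 6, 3)
  for (t in 1:3)
    expect_equal(sm[, , , t], smooth_gaussian(x[, , , t], 6, 3),
                 tolerance = 1e-12)
})

test_that("preprocess_run smooths then detrends; fused cohort path is identical", {
  spec <- tiny_spec(roi_list = list(tiny_roi()))
  co <- generate_cohort(spec)
  run <- subject_run(co, 1)
  run <- discard_initial_volumes(run, 10)
  ref <- compute_band_maps(preprocess_run(run, fwhm_mm = 6),
                           cohort_mask(spec),
                           standard_bands()[c("slow-4", "slow-5")])
  fast <- compute_cohort_maps(co, standard_bands()[c("slow-4", "slow-5")],
                              fwhm_mm = 6, subjects = 1)
  expect_equal(ref[[1]]$alff[cohort_mask(spec)], fast[[1]]$alff[, 1],
               tolerance = 1e-12)
  expect_equal(ref[[2]]$falff[cohort_mask(spec)], fast[[2]]$falff[, 1],
               tolerance = 1e-12)
})
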