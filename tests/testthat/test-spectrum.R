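bands <- standard_bands()

test_that("a bin-centred sinusoid reads off its amplitude at its bin and nowhere else", {
  n <- 100; tr <- 2
  x <- 3 * sin(2 * pi * 0.05 * (0:(n - 1)) * tr)
  sp <- amplitude_spectrum(x, tr)
  k <- which(abs(sp$frequencies - 0.05) < 1e-12)
  expect_equal(sp$amplitudes[k], 3.0, tolerance = 1e-10)
  expect_lt(max(sp$amplitudes[-k]), 1e-10)

  # slow-4 at df = 0.005 covers the 9 bins 0.030 ... 0.070
  expect_equal(sum(band_bin_mask(sp$frequencies, bands[["slow-4"]])), 9)
  expect_equal(band_alff(sp, bands[["slow-4"]]), 3 / 9, tolerance = 1e-12)
})

test_that("spectra are linear: two bin-centred sinusoids add per-bin", {
  n <- 120; tr <- 2
  t <- 0:(n - 1)
  x1 <- 2 * sin(2 * pi * (12 / (n * tr)) * t * tr)
  x2 <- 5 * cos(2 * pi * (30 / (n * tr)) * t * tr)
  a1 <- amplitude_spectrum(x1, tr)$amplitudes
  a2 <- amplitude_spectrum(x2, tr)$amplitudes
  a12 <- amplitude_spectrum(x1 + x2, tr)$amplitudes
  expect_equal(a12, sqrt(a1^2 + a2^2), tolerance = 1e-9) # disjoint bins
  expect_equal(max(abs(amplitude_spectrum(rep(4, 64), 2)$amplitudes[-1])), 0)
})

test_that("fALFF over the five canonical bands sums to one and Parseval holds", {
  set.seed(11)
  for (n in c(230, 231, 64)) {
    x <- detrend_linear(rnorm(n))
    sp <- amplitude_spectrum(x, 2)
    s <- sum(vapply(bands, function(b) falff(sp, b), numeric(1)))
    expect_equal(s, 1.0, tolerance = 1e-9)
    amp <- sp$amplitudes
    interior <- setdiff(seq_along(amp), sp$edge_bins)
    par <- (n / 2) * sum(amp[interior]^2) + n * sum(amp[sp$edge_bins]^2)
    expect_equal(par / sum(x^2), 1.0, tolerance = 1e-6)
  }
})

test_that("ALFF is scale-equivariant and fALFF scale-invariant", {
  set.seed(3)
  x <- detrend_linear(rnorm(100))
  b4 <- bands[["slow-4"]]
  for (c_ in c(0.5, 2, 17)) {
    expect_equal(band_alff(amplitude_spectrum(c_ * x, 2), b4),
                 c_ * band_alff(amplitude_spectrum(x, 2), b4),
                 tolerance = 1e-12)
    expect_equal(falff(amplitude_spectrum(c_ * x, 2), b4),
                 falff(amplitude_spectrum(x, 2), b4), tolerance = 1e-12)
  }
})

test_that("fALFF is 1 in the band holding all the energy, 0 elsewhere, NA when silent", {
  n <- 100
  x <- sin(2 * pi * 0.05 * (0:(n - 1)) * 2)
  sp <- amplitude_spectrum(x, 2)
  expect_equal(falff(sp, bands[["slow-4"]]), 1.0)
  expect_equal(falff(sp, bands[["slow-5"]]), 0.0)
  expect_true(is.na(falff(amplitude_spectrum(rep(0, 64), 2),
                          bands[["slow-4"]])))
})

test_that("band_alff rejects empty bands and short series", {
  sp <- amplitude_spectrum(rnorm(64), 2)
  expect_error(band_alff(sp, frequency_band("hi", 0.3, 0.4)), "no frequency bins")
  expect_error(amplitude_spectrum(rnorm(5), 2), ">= 8")
})

test_that("normalize_global rescales to unit in-mask mean and flags degenerate input", {
  m <- array(0, c(3, 1, 1)); m[] <- c(1, 2, 3)
  mask <- array(TRUE, c(3, 1, 1))
  expect_equal(as.vector(normalize_global(m, mask)), c(0.5, 1, 1.5))
  expect_equal(mean(normalize_global(m, mask)[mask]), 1, tolerance = 1e-12)
  u <- array(7, c(2, 2, 2))
  expect_true(all(normalize_global(u, array(TRUE, c(2, 2, 2))) == 1))
  expect_error(normalize_global(array(0, c(2, 2, 2)), array(TRUE, c(2, 2, 2))),
               "degenerate")
})

test_that("compute_band_maps: planted ROI amplitude scales ALFF linearly; global rescale invariances hold", {
  b4 <- bands[["slow-4"]]
  mask <- array(TRUE, tiny_grid)
  alff_for <- function(base) {
    spec <- tiny_spec(noise_sd = 0, drift_slope_sd = 0,
                      amplitude_jitter_sd = 0,
                      roi_list = list(tiny_roi(base = base, g1 = 1, g2 = 1)))
    run <- generate_subject_run(spec, 1L, 99L)$run
    run <- preprocess_run(run, fwhm_mm = 0)
    compute_band_maps(run, mask, list(b4))[[1]]
  }
  m1 <- alff_for(1); m2 <- alff_for(2)
  roi <- array(FALSE, tiny_grid); roi[3:6, 3:6, 3:5] <- TRUE
  expect_true(all(m1$alff[roi] > 0))
  expect_true(all(m1$alff[!roi] == 0))
  expect_equal(m2$alff[roi] / m1$alff[roi], rep(2, sum(roi)),
               tolerance = 1e-9)

  # doubling the whole run doubles raw ALFF, leaves normalized ALFF and fALFF
  spec <- tiny_spec(roi_list = list(tiny_roi()))
  run <- preprocess_run(generate_subject_run(spec, 1L, 5L)$run, fwhm_mm = 0)
  run2 <- run; run2$data <- run2$data * 2
  a <- compute_band_maps(run, mask, list(b4))[[1]]
  a2 <- compute_band_maps(run2, mask, list(b4))[[1]]
  expect_equal(a2$alff, 2 * a$alff, tolerance = 1e-9)
  expect_equal(a2$alff_norm, a$alff_norm, tolerance = 1e-9)
  expect_equal(a2$falff, a$falff, tolerance = 1e-9)

  # all-constant run: degenerate at normalization
  cst <- bold_run(array(5, c(4, 4, 4, 64)), tr = 2)
  expect_error(compute_band_maps(cst, array(TRUE, c(4, 4, 4)), list(b4)),
               "degenerate")
})
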