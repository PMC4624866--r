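#' One-sided amplitude spectrum of a BOLD time series
#'
#' Converts a (detrended) time series to the frequency domain with an FFT and
#' returns the one-sided amplitude at each bin.  The amplitude convention is
#' `2|X_k|/N` for interior bins `0 < k < N/2`, so a pure sinusoid of amplitude
#' A centred on bin k reads off as amplitude A at that bin.  The DC bin and
#' (for even N) the Nyquist bin are reported unscaled by the factor 2
#' (`|X_k|/N`) and flagged, since they have no conjugate partner.
#'
#' @param series numeric time series, length >= 8, or a T x V matrix with one
#'   series per column (all columns share the frequency grid).
#' @param tr sampling interval (repetition time) in seconds.
#' @return an `amplitude_spectrum`: list with `amplitudes` (vector, or
#'   bins x V matrix), `frequencies` (Hz), `df` (Hz), `n`, `tr`, and
#'   `edge_bins` (indices of the DC/Nyquist bins).
#' @export
amplitude_spectrum <- function(series, tr) {
  x <- if (is.matrix(series)) series else matrix(series, ncol = 1L)
  n <- nrow(x)
  if (n < 8L) stop_domain("time series must have length >= 8")
  if (!is.finite(tr) || tr <= 0) stop_domain("tr must be positive")
  if (any(!is.finite(x))) stop_domain("time series contains non-finite values")
  nb <- n %/% 2L                      # highest one-sided bin index
  X <- stats::mvfft(x)
  amp <- Mod(X[seq_len(nb + 1L), , drop = FALSE]) * (2 / n)
  amp[1L, ] <- amp[1L, ] / 2         # DC: no conjugate partner
  if (n %% 2L == 0L) amp[nb + 1L, ] <- amp[nb + 1L, ] / 2  # Nyquist, even N
  freqs <- (0:nb) / (n * tr)
  edge <- if (n %% 2L == 0L) c(1L, nb + 1L) else 1L
  structure(list(
    amplitudes = if (is.matrix(series)) amp else amp[, 1L],
    frequencies = freqs,
    df = 1 / (n * tr),
    n = n, tr = tr,
    edge_bins = edge
  ), class = "amplitude_spectrum")
}

amps_matrix <- function(spectrum) {
  a <- spectrum$amplitudes
  if (is.matrix(a)) a else matrix(a, ncol = 1L)
}

#' Band-restricted ALFF
#'
#' ALFF of a frequency band is the arithmetic mean of the one-sided amplitude
#' spectrum over the bins whose centre frequency lies in the band (DC always
#' excluded).
#'
#' @param spectrum an [amplitude_spectrum] (vector or matrix form).
#' @param band a [frequency_band].
#' @return a non-negative scalar (or one value per column for matrix input).
#' @export
band_alff <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "amplitude_spectrum"))
  sel <- band_bin_mask(spectrum$frequencies, band)
  if (!any(sel)) stop_domain("band [", band$f_low, ", ", band$f_high,
                             ") contains no frequency bins")
  out <- colMeans(amps_matrix(spectrum)[sel, , drop = FALSE])
  if (is.matrix(spectrum$amplitudes)) out else out[[1L]]
}

#' Fractional ALFF (fALFF)
#'
#' The sum of amplitudes over the band's bins divided by the sum over all
#' nonzero-frequency bins up to and including Nyquist.  The DC bin is excluded
#' from numerator and denominator.  Voxels with zero total amplitude get `NA`
#' (undefined, flagged) rather than an error.
#'
#' @inheritParams band_alff
#' @return value in `[0, 1]`, or `NA` where the total amplitude is zero.
#' @export
falff <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "amplitude_spectrum"))
  sel <- band_bin_mask(spectrum$frequencies, band)
  if (!any(sel)) stop_domain("band contains no frequency bins")
  a <- amps_matrix(spectrum)
  nonzero <- spectrum$frequencies > 1e-12
  total <- colSums(a[nonzero, , drop = FALSE])
  num <- colSums(a[sel, , drop = FALSE])
  out <- ifelse(total > 0, num / total, NA_real_)
  if (is.matrix(spectrum$amplitudes)) out else out[[1L]]
}

#' Global-mean normalization of an ALFF map
#'
#' Divides each in-mask value by the in-mask mean, the standard
#' "individual global mean" normalization that removes between-subject scale
#' differences.  Out-of-mask voxels are set to `NA`.
#'
#' @param map 3D numeric array.
#' @param mask 3D logical array of the same dimensions.
#' @return 3D array with in-mask mean exactly 1.
#' @export
normalize_global <- function(map, mask) {
  stopifnot(is.array(map), is.logical(mask), all(dim(map) == dim(mask)))
  if (!any(mask)) stop_domain("mask is empty")
  g <- mean(map[mask])
  if (!is.finite(g) || g <= 0)
    stop_domain("degenerate input: in-mask mean ALFF is not positive")
  out <- array(NA_real_, dim(map))
  out[mask] <- map[mask] / g
  out
}

#' Per-band ALFF and fALFF maps for one run
#'
#' Applies [amplitude_spectrum()] voxelwise to a preprocessed (smoothed,
#' detrended) run, then [band_alff()], [falff()] and [normalize_global()] per
#' requested band.
#'
#' @param run a `bold_run` (see [bold_run()]), already preprocessed.
#' @param mask 3D logical array on the run's grid.
#' @param bands list of [frequency_band]s; default [standard_bands()].
#' @return list with one element per band, each holding 3D arrays
#'   `alff` (raw), `alff_norm` (global-mean normalized) and `falff`,
#'   plus `df_hz`, `n`, `tr`.
#' @export
compute_band_maps <- function(run, mask, bands = standard_bands()) {
  stopifnot(inherits(run, "bold_run"))
  d <- dim(run$data)
  if (!all(d[1:3] == dim(mask))) stop_domain("mask does not match run grid")
  if (!any(mask)) stop_domain("mask is empty")
  v <- which(mask)
  ts <- t(matrix(run$data, nrow = prod(d[1:3]))[v, , drop = FALSE])
  spec <- amplitude_spectrum(ts, run$tr)
  out <- lapply(bands, function(b) {
    alff_v <- band_alff(spec, b)
    falff_v <- falff(spec, b)
    alff <- array(NA_real_, d[1:3]); alff[v] <- alff_v
    fal  <- array(NA_real_, d[1:3]); fal[v] <- falff_v
    list(band = b,
         alff = alff,
         alff_norm = normalize_global(alff, mask),
         falff = fal)
  })
  attr(out, "df_hz") <- spec$df
  attr(out, "n") <- spec$n
  attr(out, "tr") <- run$tr
  out
}
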