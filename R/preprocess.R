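#' Remove linear trend from time series
#'
#' Returns the residual of an ordinary least-squares straight-line fit, so the
#' output has exactly zero mean and zero linear slope.  Accepts a vector or a
#' T x V matrix (one series per column); the fit is computed analytically from
#' the fixed design `(1, t)`, so the matrix form is a single vectorised pass.
#'
#' @param series numeric vector (length >= 3) or T x V matrix.
#' @return detrended series, same shape.
#' @export
detrend_linear <- function(series) {
  x <- if (is.matrix(series)) series else matrix(series, ncol = 1L)
  n <- nrow(x)
  if (n < 3L) stop_domain("need at least 3 timepoints to detrend")
  t0 <- seq_len(n) - (n + 1) / 2            # centred time axis
  slope <- crossprod(t0, x) / sum(t0^2)     # 1 x V
  out <- x - rep(colMeans(x), each = n) - outer(t0, drop(slope))
  if (is.matrix(series)) out else out[, 1L]
}

gaussian_smoothing_matrix <- function(n, sigma_vox) {
  # Band matrix applying a unit-sum 1D Gaussian with replicate (nearest-edge)
  # boundary handling; sigma in voxel units. sigma == 0 -> identity.
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  off <- -r:r
  w <- exp(-off^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (j in seq_along(off)) {
    idx <- pmin(pmax(seq_len(n) + off[j], 1L), n)   # clamp = replicate edge
    K[cbind(seq_len(n), idx)] <- K[cbind(seq_len(n), idx)] + w[j]
  }
  K
}

apply_along_axis1 <- function(arr, K) {
  d <- dim(arr)
  dim(arr) <- c(d[1L], prod(d[-1L]))
  out <- K %*% arr
  dim(out) <- d
  out
}

#' Isotropic Gaussian spatial smoothing
#'
#' Separable 3D Gaussian convolution with `sigma = fwhm / (2 sqrt(2 ln 2))`
#' per axis, expressed in voxel units (`fwhm_mm / voxel_size_mm`).  The kernel
#' is normalized to unit sum and edges use nearest-edge (replicate)
#' handling, so a uniform field passes through unchanged.  `fwhm_mm = 0` is
#' the identity.  A 4D input is smoothed volume by volume (time is untouched);
#' the separable pass is implemented as one small matrix product per axis, so
#' whole runs smooth in a single vectorised sweep.
#'
#' @param x 3D volume or 4D run array.
#' @param fwhm_mm full width at half maximum of the kernel, in mm.
#' @param voxel_size_mm voxel edge lengths in mm (scalar or length 3).
#' @return array of the same shape.
#' @export
smooth_gaussian <- function(x, fwhm_mm = 6, voxel_size_mm = 3) {
  stopifnot(is.array(x), length(dim(x)) %in% c(3L, 4L))
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) stop_domain("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(x)
  vs <- rep_len(voxel_size_mm, 3L)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  d <- dim(x)
  for (axis in 1:3) {
    K <- gaussian_smoothing_matrix(d[axis], sigma[axis])
    perm <- seq_along(d); perm[c(1L, axis)] <- c(axis, 1L)
    x <- aperm(apply_along_axis1(aperm(x, perm), K), perm)
  }
  x
}

# Fused hot path for whole-cohort processing: takes a (voxels x time) matrix,
# applies the same separable Gaussian as smooth_gaussian() using cyclic axis
# rotations so the data end up in (time x voxels) layout, ready for mvfft,
# with no extra transpose.  Numerically identical to smooth_gaussian().
smooth_vt_to_tv <- function(dat_vt, dims, fwhm_mm, voxel_size_mm) {
  nt <- ncol(dat_vt)
  if (fwhm_mm <= 0) {
    out <- t(dat_vt)
    return(out)
  }
  vs <- rep_len(voxel_size_mm, 3L)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  a <- dat_vt
  dim(a) <- c(dims, nt)
  for (axis in 1:3) {
    d <- dim(a)
    K <- gaussian_smoothing_matrix(d[1L], sigma[axis])
    dim(a) <- c(d[1L], prod(d[-1L]))
    a <- K %*% a
    dim(a) <- d
    a <- aperm(a, c(2L, 3L, 4L, 1L))
  }
  dim(a) <- c(nt, prod(dims))   # (d1,d2,d3,T) rotated thrice = (T,d1,d2,d3)
  a
}

#' Preprocess a BOLD run: smooth, then detrend
#'
#' Spatial smoothing precedes the spectral analysis (mirroring the usual
#' resting-state preprocessing order); linear detrending then removes the
#' voxelwise mean and drift.  No temporal band-pass filter is applied here:
#' band restriction happens in the spectral domain (see the package vignette
#' for why pre-filtering would corrupt the fALFF denominator).
#'
#' @param run a [bold_run()].
#' @param fwhm_mm smoothing kernel FWHM in mm; 0 disables smoothing.
#' @param detrend `"linear"` or `"none"`.
#' @return a preprocessed `bold_run`.
#' @export
preprocess_run <- function(run, fwhm_mm = 6, detrend = c("linear", "none")) {
  stopifnot(inherits(run, "bold_run"))
  detrend <- match.arg(detrend)
  dat <- smooth_gaussian(run$data, fwhm_mm, run$grid$voxel_size_mm)
  if (detrend == "linear") {
    d <- dim(dat)
    m <- t(matrix(dat, nrow = prod(d[1:3])))    # T x V
    dat <- array(t(detrend_linear(m)), dim = d)
  }
  run$data <- dat
  run
}
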