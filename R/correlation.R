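#' Pearson correlation with two-tailed p value
#'
#' Product-moment correlation; the p value comes from
#' `t = r * sqrt((n - 2)/(1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3, neither constant).
#' @return list with `r`, `p`, `n`, `df`.
#' @export
pearson_corr <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) stop_domain("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_domain("degenerate input: constant vector")
  r <- stats::cor(x, y)
  df <- n - 2L
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(r * sqrt(df / (1 - r^2))), df)
  list(r = r, p = p, n = n, df = df)
}

#' Partial correlation after regressing out covariates
#'
#' Residualizes `x` and `y` on `[1, covariates]` by ordinary least squares and
#' returns the Pearson correlation of the residuals, with
#' `df = n - 2 - k` (k covariates).  With zero covariates this equals
#' [pearson_corr()] exactly.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix (n x k), e.g. columns age, sex,
#'   education; may have zero columns.
#' @return list with `r`, `p`, `n`, `df`, `k`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates) || NCOL(covariates) == 0L || length(covariates) == 0L) {
    out <- pearson_corr(x, y)
    out$k <- 0L
    return(out)
  }
  Z <- cbind(1, as.matrix(covariates))
  k <- ncol(Z) - 1L
  if (n <= k + 2L) stop_domain("need n > k + 2 observations")
  q <- qr(Z)
  if (q$rank < ncol(Z)) stop_domain("collinear covariates: matrix not full rank")
  rx <- stats::resid(stats::lm.fit(Z, x))
  ry <- stats::resid(stats::lm.fit(Z, y))
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop_domain("degenerate input: residuals are constant")
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(r * sqrt(df / (1 - r^2))), df)
  list(r = r, p = p, n = n, df = df, k = k)
}

#' Voxelwise simple regression t map
#'
#' Ordinary least-squares slope t-statistic of each voxel's value on a single
#' covariate (with intercept), `df = n - 2` — the classic within-group age
#' regression.  Voxels with zero residual variance (perfect fit) are flagged
#' degenerate and set to `NA`.
#'
#' @param maps (in-mask voxels) x subjects matrix.
#' @param covariate per-subject numeric vector (not constant).
#' @param mask 3D logical array with `sum(mask) == nrow(maps)`.
#' @return list with 3D array `t_slope`, `df`, and in-mask logical
#'   `degenerate`.
#' @export
voxelwise_regression <- function(maps, covariate, mask) {
  n <- length(covariate)
  stopifnot(is.matrix(maps), ncol(maps) == n)
  if (n < 3L) stop_domain("need at least 3 subjects")
  if (sum(mask) != nrow(maps)) stop_domain("mask size does not match maps")
  if (stats::sd(covariate) == 0) stop_domain("degenerate input: constant covariate")
  cc <- covariate - mean(covariate)
  sxx <- sum(cc^2)
  beta <- (maps %*% cc) / sxx
  fitted_dev <- outer(drop(beta), cc)
  resid <- maps - rowMeans(maps) - fitted_dev
  df <- n - 2L
  s2 <- rowSums(resid^2) / df
  # a perfect linear fit leaves only rounding error: flag it degenerate
  degenerate <- s2 <= 1e-12 * pmax(rowMeans(maps^2), .Machine$double.xmin)
  t <- drop(beta) / sqrt(s2 / sxx)
  t[degenerate] <- NA_real_
  out <- array(NA_real_, dim(mask)); out[mask] <- t
  list(t_slope = out, df = df, degenerate = degenerate)
}

#' Mean map value inside a cluster, per subject
#'
#' @param maps (in-mask voxels) x subjects matrix of per-subject maps.
#' @param cluster_mask logical vector over the same in-mask voxels (or a 3D
#'   logical array together with `mask`).
#' @param mask optional 3D logical analysis mask, needed when `cluster_mask`
#'   is a 3D array.
#' @return numeric vector, one mean per subject (column order preserved).
#' @export
extract_cluster_means <- function(maps, cluster_mask, mask = NULL) {
  stopifnot(is.matrix(maps))
  if (is.array(cluster_mask) && length(dim(cluster_mask)) == 3L) {
    if (is.null(mask)) stop_domain("need `mask` to align a 3D cluster mask")
    cluster_mask <- cluster_mask[mask]
  }
  cluster_mask <- as.logical(cluster_mask)
  if (length(cluster_mask) != nrow(maps))
    stop_domain("cluster mask does not match map rows")
  if (!any(cluster_mask)) stop_domain("cluster mask is empty")
  colMeans(maps[cluster_mask, , drop = FALSE])
}
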