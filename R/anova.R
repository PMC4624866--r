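#' 2x2 mixed-design (split-plot) ANOVA as three t-statistics
#'
#' One between-subject factor (group, 2 levels) crossed with one
#' within-subject factor (frequency band, 2 levels).  With only two within
#' levels the design collapses exactly: writing `m_i = (y4_i + y5_i)/2` and
#' `d_i = y4_i - y5_i`,
#' * the group main effect is a pooled-variance two-sample t on `m`
#'   (group 1 - group 2),
#' * the band x group interaction is a pooled-variance two-sample t on `d`
#'   (group 1 - group 2),
#' * the band main effect tests the unweighted mean of the two group means of
#'   `d` against 0, with `SE = s_d * sqrt((1/n1 + 1/n2)/4)` (groups weighted
#'   equally, the Type-III convention for unbalanced designs),
#' all on `df = n1 + n2 - 2`.  `t^2` equals the split-plot F for every effect
#' (exactly, for balanced designs).  Sign conventions: band = slow-4 - slow-5,
#' group and interaction = group 1 - group 2.
#'
#' @param y_band4,y_band5 per-subject values in the two bands (same order).
#' @param group per-subject group labels, 1 or 2 (each group needs >= 2).
#' @return data.frame with columns `effect` (`group`, `band`, `interaction`),
#'   `t`, `df`, `p` (two-tailed).
#' @export
mixed_anova_2x2 <- function(y_band4, y_band5, group) {
  n <- length(group)
  stopifnot(length(y_band4) == n, length(y_band5) == n)
  if (!all(group %in% c(1L, 2L))) stop_domain("group labels must be 1 or 2")
  n1 <- sum(group == 1L); n2 <- sum(group == 2L)
  if (n1 < 2L || n2 < 2L) stop_domain("each group needs >= 2 subjects")
  m <- (y_band4 + y_band5) / 2
  d <- y_band4 - y_band5
  df <- n1 + n2 - 2L
  pooled_var <- function(v) {
    (sum((v[group == 1L] - mean(v[group == 1L]))^2) +
     sum((v[group == 2L] - mean(v[group == 2L]))^2)) / df
  }
  s2m <- pooled_var(m); s2d <- pooled_var(d)
  if (s2m == 0 || s2d == 0)
    stop_domain("degenerate input: zero pooled variance")
  inv <- 1 / n1 + 1 / n2
  t_group <- (mean(m[group == 1L]) - mean(m[group == 2L])) / sqrt(s2m * inv)
  t_inter <- (mean(d[group == 1L]) - mean(d[group == 2L])) / sqrt(s2d * inv)
  t_band <- ((mean(d[group == 1L]) + mean(d[group == 2L])) / 2) /
    sqrt(s2d * inv / 4)
  t <- c(group = t_group, band = t_band, interaction = t_inter)
  data.frame(effect = names(t), t = unname(t), df = df,
             p = 2 * stats::pt(-abs(unname(t)), df),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Voxelwise 2x2 mixed ANOVA over subject band maps
#'
#' Applies [mixed_anova_2x2()] independently at every in-mask voxel, fully
#' vectorised.  Voxels with zero pooled variance in either derived variable
#' (subject mean or band difference) are flagged degenerate and set to `NA`
#' rather than raising an error.
#'
#' @param y_band4,y_band5 (in-mask voxels) x subjects matrices of band maps.
#' @param group per-subject group labels (1/2).
#' @param mask 3D logical array with `sum(mask) == nrow(y_band4)`.
#' @return object of class `stat_maps`: list with 3D arrays `t_group`,
#'   `t_band`, `t_interaction` (`NA` outside mask and at degenerate voxels),
#'   `df`, `n1`, `n2`, and `degenerate` (logical in-mask vector).
#' @export
voxelwise_mixed_anova <- function(y_band4, y_band5, group, mask) {
  stopifnot(is.matrix(y_band4), is.matrix(y_band5),
            all(dim(y_band4) == dim(y_band5)),
            ncol(y_band4) == length(group))
  if (sum(mask) != nrow(y_band4))
    stop_domain("mask size does not match map matrix rows")
  n1 <- sum(group == 1L); n2 <- sum(group == 2L)
  if (n1 < 2L || n2 < 2L) stop_domain("each group needs >= 2 subjects")
  df <- n1 + n2 - 2L
  m <- (y_band4 + y_band5) / 2
  d <- y_band4 - y_band5
  g1 <- group == 1L; g2 <- group == 2L
  stats_of <- function(v) {
    m1 <- rowMeans(v[, g1, drop = FALSE])
    m2 <- rowMeans(v[, g2, drop = FALSE])
    ss <- rowSums((v[, g1, drop = FALSE] - m1)^2) +
          rowSums((v[, g2, drop = FALSE] - m2)^2)
    list(m1 = m1, m2 = m2, s2 = ss / df)
  }
  sm <- stats_of(m); sd_ <- stats_of(d)
  inv <- 1 / n1 + 1 / n2
  degenerate <- sm$s2 == 0 | sd_$s2 == 0
  t_group <- (sm$m1 - sm$m2) / sqrt(sm$s2 * inv)
  t_inter <- (sd_$m1 - sd_$m2) / sqrt(sd_$s2 * inv)
  t_band <- ((sd_$m1 + sd_$m2) / 2) / sqrt(sd_$s2 * inv / 4)
  t_group[degenerate] <- t_band[degenerate] <- t_inter[degenerate] <- NA_real_
  to_map <- function(v) { a <- array(NA_real_, dim(mask)); a[mask] <- v; a }
  structure(list(t_group = to_map(t_group), t_band = to_map(t_band),
                 t_interaction = to_map(t_inter),
                 df = df, n1 = n1, n2 = n2, degenerate = degenerate),
            class = "stat_maps")
}

#' Two-tailed critical t value
#'
#' The threshold `t*` with `P(|T| > t*) = p_two_tailed` for a t-distribution
#' on `df` degrees of freedom; e.g. `critical_t(0.05, 78) = 1.9908` (printed
#' as 1.98 in typical map legends).
#'
#' @param p_two_tailed two-tailed tail probability in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @export
critical_t <- function(p_two_tailed, df) {
  if (!is.finite(p_two_tailed) || p_two_tailed <= 0 || p_two_tailed >= 1)
    stop_domain("p_two_tailed must lie in (0, 1)")
  if (!is.finite(df) || df < 1) stop_domain("df must be >= 1")
  stats::qt(1 - p_two_tailed / 2, df)
}
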