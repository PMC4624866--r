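connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop_domain("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  g[ord > 0 & ord <= switch(as.character(connectivity),
                            "6" = 1L, "18" = 2L, "26" = 3L), , drop = FALSE]
}

#' 3D connected components of a binary volume
#'
#' Labels maximal connected components under face (6), face+edge (18) or
#' face+edge+vertex (26) adjacency, by iterative vectorised minimum-label
#' propagation (each voxel repeatedly takes the smallest label among itself
#' and its foreground neighbours until a fixed point).  Labels are
#' deterministic: components are numbered 1, 2, ... by their first voxel in
#' the column-major (x fastest) scan of the volume.
#'
#' @param binary 3D logical array.
#' @param connectivity 6, 18 or 26 (default 26, vertex-touching).
#' @return list with `labels` (3D integer array, 0 = background), `sizes`
#'   (integer vector, one per component) and `n_clusters`.
#' @export
find_clusters <- function(binary, connectivity = 26L) {
  stopifnot(is.array(binary), length(dim(binary)) == 3L)
  binary <- binary & !is.na(binary)
  d <- dim(binary)
  offs <- connectivity_offsets(connectivity)
  fg <- which(binary)
  nf <- length(fg)
  if (nf == 0L)
    return(list(labels = array(0L, d), sizes = integer(0), n_clusters = 0L))
  # Work on padded linear indices so neighbour arithmetic cannot wrap around.
  pd <- d + 2L
  co <- arrayInd(fg, d)
  plin <- (co[, 1L] + 1L) + pd[1L] * co[, 2L] + pd[1L] * pd[2L] * co[, 3L]
  pos <- integer(prod(pd))
  pos[plin] <- seq_len(nf)
  doff <- offs[, 1L] + pd[1L] * offs[, 2L] + pd[1L] * pd[2L] * offs[, 3L]
  # nb[i, j]: foreground index of neighbour j of voxel i (sentinel nf+1 if
  # background).  Minimum-label propagation over this adjacency converges to
  # the per-component minimum, giving deterministic scan-order labels.
  nb <- matrix(nf + 1L, nf, length(doff))
  for (j in seq_along(doff)) {
    p <- pos[plin + doff[j]]
    hit <- p > 0L
    nb[hit, j] <- p[hit]
  }
  lab <- as.numeric(seq_len(nf))
  repeat {
    labx <- c(lab, Inf)
    new <- lab
    for (j in seq_len(ncol(nb))) new <- pmin(new, labx[nb[, j]])
    if (identical(new, lab)) break
    lab <- new
  }
  uroots <- sort(unique(lab))
  comp <- match(lab, uroots)
  labels <- array(0L, d)
  labels[fg] <- comp
  list(labels = labels,
       sizes = as.integer(tabulate(comp, length(uroots))),
       n_clusters = length(uroots))
}

#' Minimum cluster size (in voxels) implied by a strict mm^3 threshold
#'
#' For a printed rule like "cluster size > 3591 mm^3", returns the smallest
#' voxel count whose volume strictly exceeds the threshold — 134 voxels at
#' 27 mm^3 per voxel.
#'
#' @param mm3 volume threshold in cubic mm (strict `>`).
#' @param voxel_volume_mm3 volume of one voxel in cubic mm.
#' @export
cluster_threshold_from_mm3 <- function(mm3, voxel_volume_mm3) {
  as.integer(floor(mm3 / voxel_volume_mm3 + 1e-9)) + 1L
}

#' Monte Carlo (AlphaSim-style) cluster-extent threshold
#'
#' Estimates the minimum cluster extent controlling the family-wise
#' false-positive rate at level `alpha` for a given voxel-level threshold:
#' each iteration fills the mask's bounding box with independent standard
#' Gaussian noise, smooths it at the analysis smoothness, restricts to the
#' mask, standardizes to unit variance in-mask, thresholds two-tailed at
#' `voxel_p` (clusters formed separately within each sign), and records the
#' maximum cluster size across both signs.  The returned threshold is the
#' smallest k with `P(max cluster >= k) <= alpha` under the simulated null.
#'
#' @param mask 3D logical analysis mask.
#' @param voxel_p individual-voxel two-tailed p threshold, in (0, 1).
#' @param alpha target family-wise error rate, in (0, 1).
#' @param n_iterations Monte Carlo iterations (>= 100).
#' @param fwhm_mm smoothness of the simulated fields, in mm (use the applied
#'   analysis smoothing).
#' @param voxel_size_mm voxel edge in mm.
#' @param connectivity cluster-forming adjacency: 6, 18 or 26.
#' @param seed integer seed; identical config + seed gives an identical
#'   distribution.
#' @return list with `threshold_voxels`, `threshold_mm3`,
#'   `max_cluster_sizes` (per-iteration maxima), `histogram` (table of the
#'   maxima) and the configuration.
#' @export
alphasim_threshold <- function(mask, voxel_p = 0.05, alpha = 0.05,
                               n_iterations = 1000L, fwhm_mm = 6,
                               voxel_size_mm = 3, connectivity = 26L,
                               seed = 1L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop_domain("mask is empty")
  if (voxel_p <= 0 || voxel_p >= 1) stop_domain("voxel_p must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop_domain("alpha must lie in (0, 1)")
  if (n_iterations < 100L) stop_domain("need at least 100 iterations")
  d <- dim(mask)
  zthr <- stats::qnorm(1 - voxel_p / 2)
  set.seed(seed)
  max_sizes <- integer(n_iterations)
  for (it in seq_len(n_iterations)) {
    field <- array(stats::rnorm(prod(d)), d)
    if (fwhm_mm > 0) field <- smooth_gaussian(field, fwhm_mm, voxel_size_mm)
    v <- field[mask]
    v <- (v - mean(v)) / stats::sd(v)
    z <- array(0, d); z[mask] <- v
    mx <- 0L
    for (sgn in c(1, -1)) {
      excur <- array(FALSE, d)
      excur[mask] <- sgn * z[mask] > zthr
      if (any(excur)) {
        cl <- find_clusters(excur, connectivity)
        mx <- max(mx, cl$sizes)
      }
    }
    max_sizes[it] <- mx
  }
  ks <- seq_len(max(max_sizes, 1L) + 1L)
  exceed <- vapply(ks, function(k) mean(max_sizes >= k), numeric(1))
  threshold <- ks[match(TRUE, exceed <= alpha)]
  if (threshold > sum(mask))
    stop_domain("alpha = ", alpha, " unattainable: cluster threshold would ",
                "exceed the mask size")
  list(threshold_voxels = as.integer(threshold),
       threshold_mm3 = threshold * prod(rep_len(voxel_size_mm, 3)),
       max_cluster_sizes = max_sizes,
       histogram = table(max_sizes),
       config = list(voxel_p = voxel_p, alpha = alpha,
                     n_iterations = n_iterations, fwhm_mm = fwhm_mm,
                     voxel_size_mm = voxel_size_mm,
                     connectivity = connectivity, seed = seed))
}

#' Cluster-corrected report of a t map
#'
#' Binarizes a t map at the two-tailed critical value for `voxel_p`
#' (positive and negative excursions handled separately), labels connected
#' components, discards clusters smaller than `threshold_voxels`, and reports
#' each surviving cluster's size (voxels and mm^3), signed peak t, 0-based
#' peak voxel index and peak mm coordinates.
#'
#' @param t_map 3D t-statistic array (`NA` allowed outside the mask).
#' @param df degrees of freedom of the map.
#' @param voxel_p individual-voxel two-tailed p threshold.
#' @param threshold_voxels minimum cluster extent in voxels (clusters of at
#'   least this size are retained).
#' @param grid a [volume_grid()].
#' @param connectivity 6, 18 or 26.
#' @return object of class `cluster_report`: list with `table` (data.frame,
#'   one row per cluster: sign, size_voxels, size_mm3, peak_t, peak_i/j/k
#'   0-based, peak_x/y/z_mm) and `masks` (list of 3D logical cluster masks,
#'   same order).
#' @export
threshold_statmap <- function(t_map, df, voxel_p, threshold_voxels, grid,
                              connectivity = 26L) {
  stopifnot(is.array(t_map), length(dim(t_map)) == 3L)
  if (!all(dim(t_map) == grid$dims)) stop_domain("t map does not match grid")
  tcrit <- critical_t(voxel_p, df)
  vv <- voxel_volume_mm3(grid)
  rows <- list(); masks <- list()
  for (sgn in c(1, -1)) {
    excur <- !is.na(t_map) & (sgn * t_map > tcrit)
    if (!any(excur)) next
    cl <- find_clusters(excur, connectivity)
    for (lab in seq_len(cl$n_clusters)) {
      size <- cl$sizes[lab]
      if (size < threshold_voxels) next
      vox <- which(cl$labels == lab)
      peak <- vox[which.max(abs(t_map[vox]))]
      pk <- arrayInd(peak, dim(t_map))[1, ] - 1L    # 0-based
      rows[[length(rows) + 1L]] <- data.frame(
        sign = if (sgn > 0) "positive" else "negative",
        size_voxels = size, size_mm3 = size * vv,
        peak_t = t_map[peak],
        peak_i = pk[1], peak_j = pk[2], peak_k = pk[3],
        peak_x_mm = grid$origin_mm[1] + pk[1] * grid$voxel_size_mm[1],
        peak_y_mm = grid$origin_mm[2] + pk[2] * grid$voxel_size_mm[2],
        peak_z_mm = grid$origin_mm[3] + pk[3] * grid$voxel_size_mm[3],
        stringsAsFactors = FALSE)
      masks[[length(masks) + 1L]] <- cl$labels == lab
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sign = character(), size_voxels = integer(),
               size_mm3 = numeric(), peak_t = numeric(),
               peak_i = integer(), peak_j = integer(), peak_k = integer(),
               peak_x_mm = numeric(), peak_y_mm = numeric(),
               peak_z_mm = numeric(), stringsAsFactors = FALSE)
  if (nrow(table)) {
    ord <- order(-table$size_voxels)
    table <- table[ord, , drop = FALSE]
    rownames(table) <- NULL
    masks <- masks[ord]
  }
  structure(list(table = table, masks = masks,
                 voxel_p = voxel_p, df = df, t_critical = tcrit,
                 threshold_voxels = as.integer(threshold_voxels)),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> voxel p < %g (|t| > %.4f, df = %d), extent >= %d voxels: %d cluster(s)\n",
              x$voxel_p, x$t_critical, x$df, x$threshold_voxels,
              nrow(x$table)))
  if (nrow(x$table)) print(x$table, ...)
  invisible(x)
}

#' Dice overlap between two binary volumes
#' @param a,b 3D logical arrays of identical dimensions.
#' @return `2|A and B| / (|A| + |B|)`, or `NA` if both are empty.
#' @export
dice_overlap <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(NA_real_)
  2 * sum(a & b) / (sa + sb)
}
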