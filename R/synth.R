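#' Synthetic cohort specification
#'
#' Describes a synthetic resting-state cohort: group sizes, acquisition grid,
#' run length and TR, regions with planted band-limited signal, noise and
#' drift levels, clinical-covariate couplings, and the fraction of subjects
#' designated as head-motion outliers.  Defaults mirror a typical 3 T
#' resting-state protocol (240 volumes at TR = 2 s on a 3 mm isotropic grid)
#' at desk scale (24 x 28 x 24 voxels rather than full MNI coverage).
#'
#' @param n_group1,n_group2 subjects per group (group 1 = patients,
#'   group 2 = controls); each >= 2.
#' @param grid_dims grid dimensions in voxels, length 3.
#' @param voxel_size_mm isotropic voxel edge in mm.
#' @param n_timepoints acquired volumes per run (default 240).
#' @param tr_seconds repetition time in seconds (default 2).
#' @param roi_list list of [roi_definition()]s with planted signal.
#' @param noise_sd SD of broadband white noise, in signal units.
#' @param drift_slope_sd SD of the per-voxel linear drift slope, in signal
#'   units per volume.
#' @param covariate_couplings list of [coupling_spec()]s.
#' @param motion_outlier_fraction fraction of each group designated as motion
#'   outliers (one axis driven past the 2.0 mm / 2.0 deg limit).
#' @param amplitude_jitter_sd SD of the log-normal between-subject jitter on
#'   ROI signal amplitude; gives planted amplitudes realistic
#'   between-subject spread (and something for covariates to couple to).
#' @param baseline mean signal level added to every voxel.
#' @param seed master seed; every subject and stage derives a named
#'   sub-stream from it via [substream_seed()].
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_group1, n_group2,
                           grid_dims = c(24L, 28L, 24L),
                           voxel_size_mm = 3,
                           n_timepoints = 240L,
                           tr_seconds = 2,
                           roi_list = list(),
                           noise_sd = 1,
                           drift_slope_sd = 0.005,
                           covariate_couplings = list(),
                           motion_outlier_fraction = 0,
                           amplitude_jitter_sd = 0.3,
                           baseline = 100,
                           seed = 1L) {
  if (n_group1 < 2L || n_group2 < 2L) stop_domain("each group needs >= 2 subjects")
  if (n_timepoints < 18L) stop_domain("n_timepoints must be >= 18")
  if (tr_seconds <= 0) stop_domain("tr_seconds must be positive")
  if (voxel_size_mm <= 0) stop_domain("voxel_size_mm must be positive")
  if (motion_outlier_fraction < 0 || motion_outlier_fraction > 1)
    stop_domain("motion_outlier_fraction must lie in [0, 1]")
  if (noise_sd < 0 || drift_slope_sd < 0 || amplitude_jitter_sd < 0)
    stop_domain("noise_sd, drift_slope_sd and amplitude_jitter_sd must be >= 0")
  grid_dims <- as.integer(rep_len(grid_dims, 3L))
  for (roi in roi_list) {
    stopifnot(inherits(roi, "roi_definition"))
    if (any(roi$voxel_set < 1L) ||
        any(t(roi$voxel_set) > grid_dims))
      stop_domain("ROI '", roi$name, "' has voxels outside the grid")
  }
  roi_names <- vapply(roi_list, `[[`, "", "name")
  for (cp in covariate_couplings) {
    stopifnot(inherits(cp, "coupling_spec"))
    if (!cp$roi_name %in% roi_names)
      stop_domain("coupling refers to unknown ROI '", cp$roi_name, "'")
  }
  structure(list(
    n_group1 = as.integer(n_group1), n_group2 = as.integer(n_group2),
    grid_dims = grid_dims, voxel_size_mm = voxel_size_mm,
    n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
    roi_list = roi_list, noise_sd = noise_sd,
    drift_slope_sd = drift_slope_sd,
    covariate_couplings = covariate_couplings,
    motion_outlier_fraction = motion_outlier_fraction,
    amplitude_jitter_sd = amplitude_jitter_sd,
    baseline = baseline, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Region with planted band-limited signal
#'
#' @param name ROI label.
#' @param voxel_set n x 3 integer matrix of 1-based voxel indices.
#' @param band the [frequency_band] in which signal is planted.
#' @param base_amplitude SD of the planted oscillation for a multiplier of 1.
#' @param group1_multiplier,group2_multiplier group-specific amplitude scaling
#'   (>= 0); unequal multipliers plant a group x band interaction.
#' @return object of class `roi_definition`.
#' @export
roi_definition <- function(name, voxel_set, band, base_amplitude = 1,
                           group1_multiplier = 1, group2_multiplier = 1) {
  voxel_set <- matrix(as.integer(voxel_set), ncol = 3L)
  if (nrow(voxel_set) == 0L) stop_domain("ROI voxel set is empty")
  if (base_amplitude < 0 || group1_multiplier < 0 || group2_multiplier < 0)
    stop_domain("amplitudes and multipliers must be >= 0")
  stopifnot(inherits(band, "frequency_band"))
  structure(list(name = name, voxel_set = voxel_set, band = band,
                 base_amplitude = base_amplitude,
                 group1_multiplier = group1_multiplier,
                 group2_multiplier = group2_multiplier),
            class = "roi_definition")
}

#' Axis-aligned box ROI helper
#' @param name ROI label.
#' @param from,to 1-based inclusive corner indices, length 3.
#' @inheritParams roi_definition
#' @export
roi_box <- function(name, from, to, band, base_amplitude = 1,
                    group1_multiplier = 1, group2_multiplier = 1) {
  vox <- as.matrix(expand.grid(from[1]:to[1], from[2]:to[2], from[3]:to[3]))
  colnames(vox) <- NULL
  roi_definition(name, vox, band, base_amplitude,
                 group1_multiplier, group2_multiplier)
}

#' Clinical covariate coupled to planted ROI amplitude
#'
#' The covariate is generated as
#' `y = r * z(a) + sqrt(1 - r^2) * e`, where `a` is the noiseless planted
#' amplitude of the named ROI across group-1 subjects, so its population
#' correlation with the planted amplitude is exactly `target_r`.
#'
#' @param covariate_name `"thq"` or `"duration_months"`.
#' @param roi_name name of an ROI defined in the cohort specification.
#' @param target_r population correlation in `[-1, 1]`.
#' @return object of class `coupling_spec`.
#' @export
coupling_spec <- function(covariate_name, roi_name, target_r) {
  if (abs(target_r) > 1) stop_domain("|target_r| must be <= 1")
  structure(list(covariate_name = covariate_name, roi_name = roi_name,
                 target_r = target_r),
            class = "coupling_spec")
}

#' Band-limited oscillatory signal
#'
#' Synthesizes a zero-mean series whose one-sided amplitude spectrum is zero
#' outside the band and whose sample SD equals `target_sd`, by spectrally
#' masking white noise (zeroing every FFT bin whose centre frequency falls
#' outside the band, plus DC) and rescaling — this keeps the broadband
#' character of BOLD low-frequency oscillations rather than a sum of a few
#' sinusoids.
#'
#' @param n_timepoints series length (>= 8).
#' @param tr sampling interval in seconds.
#' @param band a [frequency_band] inside `(0, Nyquist]`.
#' @param target_sd desired sample SD (>= 0).
#' @param seed integer seed.
#' @return numeric series of length `n_timepoints`.
#' @export
plant_band_signal <- function(n_timepoints, tr, band, target_sd, seed) {
  n <- as.integer(n_timepoints)
  if (n < 8L) stop_domain("n_timepoints must be >= 8")
  if (target_sd < 0) stop_domain("target_sd must be >= 0")
  nyq <- 1 / (2 * tr)
  if (band$f_high > nyq + 1e-12 || band$f_low < 0)
    stop_domain("invalid band: must lie within (0, Nyquist = ", nyq, " Hz]")
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) / (n * tr)          # mirrored bin-centre frequencies
  keep <- band_bin_mask(f, band)
  if (!any(keep))
    stop_domain("invalid band: no frequency bins fall inside [",
                band$f_low, ", ", band$f_high, ")")
  if (target_sd == 0) return(numeric(n))
  set.seed(seed)
  X <- stats::fft(stats::rnorm(n))
  X[!keep] <- 0+0i
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x <- x - mean(x)
  x * (target_sd / stats::sd(x))
}

#' Covariate with a planted correlation
#'
#' Returns `y = target_r * z(x) + sqrt(1 - target_r^2) * e` with `e`
#' independent standard normal noise and `z` the standardization of `x`, so
#' the population correlation of `y` with `x` is `target_r` (and exactly 1 in
#' sample when `target_r = 1`).
#'
#' @param x numeric vector (length >= 3, not constant).
#' @param target_r correlation in `[-1, 1]`.
#' @param seed integer seed.
#' @return numeric vector on the standardized scale.
#' @export
plant_covariate <- function(x, target_r, seed) {
  if (length(x) < 3L) stop_domain("need at least 3 values")
  if (abs(target_r) > 1) stop_domain("|target_r| must be <= 1")
  sx <- stats::sd(x)
  if (!is.finite(sx) || sx == 0) stop_domain("degenerate input: x is constant")
  z <- (x - mean(x)) / sx
  set.seed(seed)
  e <- stats::rnorm(length(x))
  target_r * z + sqrt(1 - target_r^2) * e
}

# Per-subject ROI amplitudes: base * group multiplier * log-normal jitter.
subject_roi_amplitudes <- function(spec, group, subject_seed) {
  if (length(spec$roi_list) == 0L) return(numeric(0))
  set.seed(substream_seed(subject_seed, "amplitude"))
  jitter <- exp(stats::rnorm(length(spec$roi_list), 0,
                             spec$amplitude_jitter_sd))
  a <- vapply(seq_along(spec$roi_list), function(j) {
    roi <- spec$roi_list[[j]]
    mult <- if (group == 1L) roi$group1_multiplier else roi$group2_multiplier
    roi$base_amplitude * mult * jitter[j]
  }, numeric(1))
  names(a) <- vapply(spec$roi_list, `[[`, "", "name")
  a
}

generate_motion_trace_internal <- function(n, outlier, seed) {
  set.seed(seed)
  K <- gaussian_smoothing_matrix(n, 6)
  m <- K %*% matrix(stats::rnorm(n * 6L), n, 6L)
  peak_target <- stats::runif(6L, 0.05, 0.8)
  for (j in 1:6) {
    mx <- max(abs(m[, j]))
    m[, j] <- if (mx > 0) m[, j] * peak_target[j] / mx else m[, j]
  }
  if (outlier) {
    j <- sample.int(6L, 1L)
    t0 <- sample(seq(5L, n - 4L), 1L)
    w <- stats::runif(1, 3, 8)
    peak <- 2.0 + stats::runif(1, 0.3, 1.2)
    sgn <- if (m[t0, j] >= 0) 1 else -1   # constructive at the bump centre
    m[, j] <- m[, j] + sgn * peak * exp(-(seq_len(n) - t0)^2 / (2 * w^2))
  }
  motion_trace(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE])
}

#' Generate one subject's 4D run (and motion trace)
#'
#' Each voxel's series is baseline + linear drift (per-voxel slope drawn with
#' SD `drift_slope_sd`) + white noise (SD `noise_sd`); ROI voxels additionally
#' carry the ROI's shared band-limited signal scaled by the subject's planted
#' amplitude (base amplitude x group multiplier x subject jitter).
#'
#' @param spec a [synthetic_spec()].
#' @param group subject's group, 1 or 2.
#' @param subject_seed integer seed for this subject.
#' @param outlier designate this subject as a motion outlier?
#' @return list with `run` ([bold_run()]), `motion` ([motion_trace()], over
#'   the volumes retained after discarding the first 10), and `amplitudes`
#'   (named per-ROI planted amplitude).
#' @export
generate_subject_run <- function(spec, group, subject_seed, outlier = FALSE) {
  g <- generate_subject_matrix(spec, group, subject_seed)
  nt <- spec$n_timepoints
  run <- bold_run(array(g$dat, c(spec$grid_dims, nt)), tr = spec$tr_seconds,
                  voxel_size_mm = spec$voxel_size_mm)
  amps <- g$amplitudes
  motion <- generate_motion_trace_internal(
    max(nt - 10L, 8L), outlier, substream_seed(subject_seed, "motion"))
  list(run = run, motion = motion, amplitudes = amps)
}

# Voxels x time signal matrix for one subject (column-major voxel order).
generate_subject_matrix <- function(spec, group, subject_seed) {
  if (!group %in% c(1L, 2L)) stop_domain("group must be 1 or 2")
  dims <- spec$grid_dims
  nt <- spec$n_timepoints
  nv <- prod(dims)
  set.seed(substream_seed(subject_seed, "noise"))
  dat <- if (spec$noise_sd > 0)
    matrix(stats::rnorm(nv * nt, sd = spec$noise_sd), nv, nt)
  else matrix(0, nv, nt)
  if (spec$drift_slope_sd > 0) {
    set.seed(substream_seed(subject_seed, "drift"))
    slopes <- stats::rnorm(nv, sd = spec$drift_slope_sd)
    dat <- dat + outer(slopes, 0:(nt - 1L))
  }
  dat <- dat + spec$baseline
  amps <- subject_roi_amplitudes(spec, group, subject_seed)
  for (j in seq_along(spec$roi_list)) {
    roi <- spec$roi_list[[j]]
    if (amps[j] == 0) next
    sig <- plant_band_signal(nt, spec$tr_seconds, roi$band, 1.0,
                             substream_seed(subject_seed,
                                            paste0("roi-", roi$name)))
    lin <- roi$voxel_set[, 1L] +
      dims[1L] * (roi$voxel_set[, 2L] - 1L) +
      dims[1L] * dims[2L] * (roi$voxel_set[, 3L] - 1L)
    dat[lin, ] <- dat[lin, ] + rep(amps[j] * sig, each = length(lin))
  }
  list(dat = dat, amplitudes = amps)
}

covariate_scales <- list(
  thq = list(location = 43.5, scale = 21.3, min = 0, max = 100),
  duration_months = list(location = 36.9, scale = 30, min = 1, max = 240)
)

#' Generate a synthetic cohort
#'
#' Produces phenotype records, motion traces, designated motion outliers,
#' planted ROI amplitudes and (on demand) the 4D runs for
#' `n_group1 + n_group2` subjects.  Runs are not stored by default — use
#' [subject_run()] to (re)generate any subject's run deterministically from
#' the cohort's seeds — so large cohorts stream through downstream stages one
#' subject at a time.
#'
#' Outlier designation: `round(fraction * n)` subjects per group, the first k
#' of each group after a seeded shuffle.  Clinical covariates named in
#' `covariate_couplings` are generated from the noiseless planted amplitudes
#' of group-1 subjects via [plant_covariate()] and mapped to their natural
#' scale (THQ: 43.5 +/- 21.3 clipped to 0-100; duration: months, floored at
#' 1); uncoupled covariates are drawn from the same marginals independently.
#'
#' @param spec a [synthetic_spec()].
#' @param keep_runs also store every generated run in memory (only sensible
#'   for small cohorts/grids).
#' @return object of class `synthetic_cohort`: list with `spec`, `pheno`
#'   (data.frame with subject_id, group, age, sex, education_years, thq,
#'   duration_months, motion_outlier, subject_seed), `motions` (list of
#'   [motion_trace()]), `amplitudes` (subjects x ROIs matrix), and `runs` if
#'   requested.
#' @export
generate_cohort <- function(spec, keep_runs = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n1 <- spec$n_group1; n2 <- spec$n_group2; n <- n1 + n2
  group <- rep(c(1L, 2L), c(n1, n2))
  id <- sprintf("sub-%03d", seq_len(n))
  subject_seed <- vapply(id, function(s)
    substream_seed(spec$seed, paste0("subject-", s)), integer(1))

  outlier <- logical(n)
  for (g in 1:2) {
    members <- which(group == g)
    k <- round(spec$motion_outlier_fraction * length(members))
    if (k > 0L) {
      set.seed(substream_seed(spec$seed, paste0("outliers-group", g)))
      outlier[members[sample.int(length(members))][seq_len(k)]] <- TRUE
    }
  }

  amps <- matrix(0, n, length(spec$roi_list),
                 dimnames = list(id, vapply(spec$roi_list, `[[`, "", "name")))
  for (i in seq_len(n))
    if (length(spec$roi_list) > 0L)
      amps[i, ] <- subject_roi_amplitudes(spec, group[i], subject_seed[i])

  set.seed(substream_seed(spec$seed, "pheno"))
  age <- pmin(pmax(round(stats::rnorm(n, 41.5, 14.6)), 20), 70)
  sex <- stats::rbinom(n, 1L, 0.5)
  education <- sample(8:19, n, replace = TRUE)
  thq <- ifelse(group == 1L,
                pmin(pmax(stats::rnorm(n, 43.5, 21.3), 0), 100), NA_real_)
  duration <- ifelse(group == 1L,
                     pmax(stats::rnorm(n, 36.9, 30), 1), NA_real_)
  pheno <- data.frame(subject_id = id, group = group, age = age, sex = sex,
                      education_years = education, thq = round(thq, 1),
                      duration_months = round(duration, 1),
                      motion_outlier = outlier,
                      subject_seed = subject_seed,
                      stringsAsFactors = FALSE, row.names = NULL)

  g1 <- which(group == 1L)
  for (cp in spec$covariate_couplings) {
    x <- amps[g1, cp$roi_name]
    y <- plant_covariate(x, cp$target_r,
                         substream_seed(spec$seed,
                                        paste0("coupling-", cp$covariate_name)))
    sc <- covariate_scales[[cp$covariate_name]] %||%
      list(location = 0, scale = 1, min = -Inf, max = Inf)
    pheno[[cp$covariate_name]][g1] <-
      round(pmin(pmax(sc$location + sc$scale * y, sc$min), sc$max), 1)
  }

  motions <- lapply(seq_len(n), function(i)
    generate_motion_trace_internal(max(spec$n_timepoints - 10L, 8L),
                                   outlier[i],
                                   substream_seed(subject_seed[i], "motion")))
  cohort <- structure(list(spec = spec, pheno = pheno, motions = motions,
                           amplitudes = amps),
                      class = "synthetic_cohort")
  if (keep_runs)
    cohort$runs <- lapply(seq_len(n), function(i) subject_run(cohort, i))
  cohort
}

#' Regenerate one cohort subject's run
#' @param cohort a [generate_cohort()] result.
#' @param i subject index.
#' @return a [bold_run()].
#' @export
subject_run <- function(cohort, i) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ph <- cohort$pheno[i, ]
  generate_subject_run(cohort$spec, ph$group, ph$subject_seed,
                       ph$motion_outlier)$run
}

#' All-true analysis mask for a spec's grid
#' @param spec a [synthetic_spec()].
#' @export
cohort_mask <- function(spec) array(TRUE, spec$grid_dims)

#' Write a cohort to disk in standard formats
#'
#' BOLD runs as 4D NIfTI-1, motion traces as 6-column text, phenotype as TSV,
#' plus the analysis mask as 3D NIfTI.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort$pheno))) {
    id <- cohort$pheno$subject_id[i]
    write_bold_nifti(subject_run(cohort, i),
                     file.path(dir, paste0(id, "_bold.nii.gz")))
    write_motion_text(cohort$motions[[i]],
                      file.path(dir, paste0(id, "_motion.txt")))
  }
  write_pheno_tsv(cohort$pheno, file.path(dir, "participants.tsv"))
  write_map_nifti(cohort_mask(cohort$spec) + 0,
                  volume_grid(cohort$spec$grid_dims,
                              cohort$spec$voxel_size_mm),
                  file.path(dir, "mask.nii.gz"))
  invisible(dir)
}

#' Per-subject band maps for a whole cohort
#'
#' Streams through the cohort one subject at a time: regenerate the run,
#' discard initial volumes, smooth and detrend, compute ALFF / normalized
#' ALFF / fALFF per band, and keep only the in-mask values.
#'
#' @param cohort a [generate_cohort()] result.
#' @param bands list of [frequency_band]s.
#' @param mask 3D logical array (default: all voxels).
#' @param fwhm_mm smoothing FWHM in mm (0 disables).
#' @param n_discard initial volumes to drop.
#' @param subjects subject indices to process (default: all).
#' @return list with one element per band, each containing matrices
#'   `alff`, `alff_norm`, `falff` of size (in-mask voxels) x (subjects);
#'   plus attributes `mask` and `grid`.
#' @export
compute_cohort_maps <- function(cohort, bands = standard_bands(),
                                mask = NULL, fwhm_mm = 6, n_discard = 10L,
                                subjects = seq_len(nrow(cohort$pheno))) {
  spec <- cohort$spec
  if (is.null(mask)) mask <- cohort_mask(spec)
  nv <- sum(mask)
  out <- lapply(bands, function(b)
    list(alff = matrix(NA_real_, nv, length(subjects)),
         alff_norm = matrix(NA_real_, nv, length(subjects)),
         falff = matrix(NA_real_, nv, length(subjects))))
  names(out) <- vapply(bands, `[[`, "", "name")
  nt <- spec$n_timepoints
  if (n_discard >= nt) stop_domain("cannot discard ", n_discard, " of ",
                                   nt, " volumes")
  mvec <- as.vector(mask)
  for (s in seq_along(subjects)) {
    i <- subjects[s]
    gm <- generate_subject_matrix(spec, cohort$pheno$group[i],
                                  cohort$pheno$subject_seed[i])
    dat <- gm$dat[, (n_discard + 1L):nt, drop = FALSE]
    ts <- smooth_vt_to_tv(dat, spec$grid_dims, fwhm_mm, spec$voxel_size_mm)
    ts <- detrend_linear(ts)
    sp <- amplitude_spectrum(ts, spec$tr_seconds)
    for (b in seq_along(bands)) {
      alff_all <- band_alff(sp, bands[[b]])
      g <- mean(alff_all[mvec])
      if (!is.finite(g) || g <= 0)
        stop_domain("degenerate input: in-mask mean ALFF is not positive")
      out[[b]]$alff[, s] <- alff_all[mvec]
      out[[b]]$alff_norm[, s] <- alff_all[mvec] / g
      out[[b]]$falff[, s] <- falff(sp, bands[[b]])[mvec]
    }
  }
  attr(out, "mask") <- mask
  attr(out, "grid") <- volume_grid(spec$grid_dims, spec$voxel_size_mm)
  attr(out, "subjects") <- subjects
  out
}
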