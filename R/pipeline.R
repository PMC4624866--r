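#' Default pipeline configuration
#'
#' A desk-scale synthetic run: 12 + 12 subjects on a 24 x 28 x 24 grid of
#' 3 mm voxels, 240 volumes at TR = 2 s, two planted regions (one with a
#' group effect in both analysed bands, one with a group x band interaction
#' in slow-4) and clinical covariates coupled to the planted amplitudes.
#'
#' @param seed master seed for the run.
#' @return a named list accepted by [run_full_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    n_group1 = 12L, n_group2 = 12L,
    grid_dims = c(24L, 28L, 24L), voxel_size_mm = 3,
    n_timepoints = 240L, tr_seconds = 2,
    n_discard = 10L, fwhm_mm = 6,
    max_translation_mm = 2.0, max_rotation_deg = 2.0,
    noise_sd = 1, drift_slope_sd = 0.005,
    motion_outlier_fraction = 0, amplitude_jitter_sd = 0.3,
    rois = list(
      list(name = "frontal", from = c(4L, 18L, 14L), to = c(10L, 24L, 20L),
           bands = c("slow-4", "slow-5"), base_amplitude = 1,
           group1_multiplier = 1.4, group2_multiplier = 1.0),
      list(name = "orbitofrontal", from = c(14L, 6L, 4L), to = c(20L, 12L, 10L),
           bands = "slow-4", base_amplitude = 1,
           group1_multiplier = 1.5, group2_multiplier = 1.0)
    ),
    couplings = list(
      list(covariate = "thq", roi = "frontal_slow-4", target_r = 0.5),
      list(covariate = "duration_months", roi = "frontal_slow-5",
           target_r = 0.5)
    ),
    analysis_bands = c("slow-4", "slow-5"),
    metrics = c("alff_norm", "falff"),
    voxel_p = 0.05, alpha = 0.05,
    alphasim_iterations = 1000L, connectivity = 26L
  )
}

config_to_spec <- function(config) {
  bands <- standard_bands()
  rois <- list()
  for (r in config$rois %||% list()) {
    for (bn in r$bands) {
      if (!bn %in% names(bands)) stop_domain("unknown band '", bn, "' in ROI")
      rois[[length(rois) + 1L]] <- roi_box(
        paste0(r$name, "_", bn), r$from, r$to, bands[[bn]],
        base_amplitude = r$base_amplitude %||% 1,
        group1_multiplier = r$group1_multiplier %||% 1,
        group2_multiplier = r$group2_multiplier %||% 1)
    }
  }
  couplings <- lapply(config$couplings %||% list(), function(cp)
    coupling_spec(cp$covariate, cp$roi, cp$target_r))
  synthetic_spec(
    n_group1 = config$n_group1, n_group2 = config$n_group2,
    grid_dims = config$grid_dims, voxel_size_mm = config$voxel_size_mm,
    n_timepoints = config$n_timepoints, tr_seconds = config$tr_seconds,
    roi_list = rois, noise_sd = config$noise_sd,
    drift_slope_sd = config$drift_slope_sd,
    covariate_couplings = couplings,
    motion_outlier_fraction = config$motion_outlier_fraction %||% 0,
    amplitude_jitter_sd = config$amplitude_jitter_sd %||% 0.3,
    seed = substream_seed(config$seed, "cohort"))
}

validate_pipeline_config <- function(config) {
  defaults <- default_pipeline_config()
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("n_group1", "n_group2", "n_timepoints", "n_discard",
               "alphasim_iterations"))
    if (!is.numeric(config[[nm]]) || config[[nm]] < 0)
      stop_domain("config error at '", nm, "': must be a non-negative number")
  for (nm in c("voxel_p", "alpha"))
    if (config[[nm]] <= 0 || config[[nm]] >= 1)
      stop_domain("config error at '", nm, "': must lie in (0, 1)")
  if (!all(config$analysis_bands %in% names(standard_bands())))
    stop_domain("config error at 'analysis_bands': unknown band name")
  if (!all(config$metrics %in% c("alff", "alff_norm", "falff")))
    stop_domain("config error at 'metrics': must be alff, alff_norm or falff")
  config
}

#' Run the full band-specific ALFF/fALFF analysis
#'
#' Orchestrates simulate -> motion QC -> preprocess -> band ALFF/fALFF ->
#' voxelwise 2x2 mixed ANOVA -> Monte Carlo cluster-extent threshold ->
#' cluster report -> clinical correlations, as one reproducible run.  All
#' randomness derives from `config$seed` through named sub-streams, so
#' identical configurations give identical outputs.
#'
#' @param config a named list (see [default_pipeline_config()]) or a path to
#'   a JSON file with the same fields.
#' @param out_dir optional directory; when given, t maps (NIfTI), cluster and
#'   correlation tables (TSV) and a provenance JSON are written under
#'   `out_dir/derivatives/<stage>/`.
#' @param verbose print stage progress.
#' @return list with `config`, `cohort` (phenotype and QC decisions),
#'   `retained` (indices), `maps` (per-band in-mask matrices), `anova` (per
#'   metric [voxelwise_mixed_anova()] results), `alphasim`, `clusters` (per
#'   metric x effect [threshold_statmap()] reports), and `correlations`
#'   (tidy data.frame of cluster-mean vs covariate tests).
#' @export
run_full_pipeline <- function(config = default_pipeline_config(),
                              out_dir = NULL, verbose = FALSE) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE,
                                  simplifyMatrix = FALSE)
  config <- validate_pipeline_config(config)
  say <- function(...) if (verbose) message(...)
  bands <- standard_bands()[config$analysis_bands]

  say("stage simulate: generating cohort")
  spec <- config_to_spec(config)
  cohort <- generate_cohort(spec)
  mask <- cohort_mask(spec)
  grid <- volume_grid(spec$grid_dims, spec$voxel_size_mm)

  say("stage qc: screening motion")
  keep <- screen_cohort_motion(cohort$motions, config$max_translation_mm,
                               config$max_rotation_deg)
  retained <- which(keep)
  group <- cohort$pheno$group[retained]
  if (sum(group == 1L) < 2L || sum(group == 2L) < 2L)
    stop_domain("fewer than 2 subjects per group retained after motion QC")

  say("stage alff: computing band maps for ", length(retained), " subjects")
  maps <- compute_cohort_maps(cohort, bands, mask = mask,
                              fwhm_mm = config$fwhm_mm,
                              n_discard = config$n_discard,
                              subjects = retained)

  say("stage stats: voxelwise mixed ANOVA")
  b4 <- config$analysis_bands[1]; b5 <- config$analysis_bands[2]
  anova <- lapply(config$metrics, function(metric)
    voxelwise_mixed_anova(maps[[b4]][[metric]], maps[[b5]][[metric]],
                          group, mask))
  names(anova) <- config$metrics

  say("stage cluster-sim: AlphaSim threshold (",
      config$alphasim_iterations, " iterations)")
  asim <- alphasim_threshold(mask, config$voxel_p, config$alpha,
                             config$alphasim_iterations, config$fwhm_mm,
                             config$voxel_size_mm, config$connectivity,
                             seed = substream_seed(config$seed, "alphasim"))

  say("stage report: cluster-corrected maps")
  effects <- c(group = "t_group", band = "t_band",
               interaction = "t_interaction")
  clusters <- lapply(config$metrics, function(metric) {
    lapply(effects, function(eff)
      threshold_statmap(anova[[metric]][[eff]], anova[[metric]]$df,
                        config$voxel_p, asim$threshold_voxels, grid,
                        config$connectivity))
  })
  names(clusters) <- config$metrics

  say("stage correlate: cluster means vs clinical covariates")
  correlations <- correlate_clusters(maps, clusters, cohort, retained,
                                     config)

  result <- list(config = config, spec = spec,
                 cohort = cohort[c("pheno", "amplitudes")],
                 retained = retained, mask = mask, grid = grid,
                 maps = maps, anova = anova, alphasim = asim,
                 clusters = clusters, correlations = correlations)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# Pearson and partial (age, sex, education-adjusted) correlations between
# cluster means and patient covariates, for every surviving cluster of the
# group and interaction effects, in both analysed bands.
correlate_clusters <- function(maps, clusters, cohort, retained, config) {
  pheno <- cohort$pheno[retained, ]
  g1 <- which(pheno$group == 1L)
  rows <- list()
  if (length(g1) >= 5L) {
    covm <- as.matrix(pheno[g1, c("age", "sex", "education_years")])
    for (metric in names(clusters)) {
      for (eff in c("group", "interaction")) {
        rep_ <- clusters[[metric]][[eff]]
        if (nrow(rep_$table) == 0L) next
        for (ci in seq_len(nrow(rep_$table))) {
          # which band differs most at the cluster peak
          peaks <- vapply(config$analysis_bands, function(bn) {
            vals <- extract_cluster_means(maps[[bn]][[metric]],
                                          rep_$masks[[ci]],
                                          attr(maps, "mask"))
            abs(mean(vals[pheno$group == 1L]) - mean(vals[pheno$group == 2L]))
          }, numeric(1))
          for (bn in config$analysis_bands) {
            vals <- extract_cluster_means(maps[[bn]][[metric]],
                                          rep_$masks[[ci]],
                                          attr(maps, "mask"))[g1]
            for (cov_name in c("thq", "duration_months")) {
              y <- pheno[[cov_name]][g1]
              if (all(is.na(y)) || stats::sd(y, na.rm = TRUE) == 0) next
              pc <- pearson_corr(vals, y)
              pp <- partial_corr(vals, y, covm)
              rows[[length(rows) + 1L]] <- data.frame(
                metric = metric, effect = eff, cluster = ci,
                band = bn, winning_band = names(which.max(peaks)),
                covariate = cov_name,
                r = pc$r, p = pc$p,
                r_partial = pp$r, p_partial = pp$p,
                n = pc$n, stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(metric = character(), effect = character(),
               cluster = integer(), band = character(),
               winning_band = character(), covariate = character(),
               r = numeric(), p = numeric(), r_partial = numeric(),
               p_partial = numeric(), n = integer(),
               stringsAsFactors = FALSE)
}

write_pipeline_outputs <- function(result, out_dir) {
  stage_dir <- function(s) {
    p <- file.path(out_dir, "derivatives", s)
    dir.create(p, recursive = TRUE, showWarnings = FALSE)
    p
  }
  qc <- stage_dir("qc")
  write_pheno_tsv(result$cohort$pheno, file.path(qc, "participants.tsv"))
  utils::write.table(
    data.frame(subject_id = result$cohort$pheno$subject_id,
               retained = seq_len(nrow(result$cohort$pheno)) %in%
                 result$retained),
    file.path(qc, "motion_qc.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  st <- stage_dir("stats")
  for (metric in names(result$anova)) {
    for (eff in c("t_group", "t_band", "t_interaction"))
      write_map_nifti(result$anova[[metric]][[eff]], result$grid,
                      file.path(st, paste0(metric, "_", eff, ".nii.gz")))
  }
  cs <- stage_dir("cluster-sim")
  jsonlite::write_json(
    list(threshold_voxels = result$alphasim$threshold_voxels,
         threshold_mm3 = result$alphasim$threshold_mm3,
         config = result$alphasim$config,
         max_cluster_sizes = result$alphasim$max_cluster_sizes),
    file.path(cs, "alphasim.json"), auto_unbox = TRUE, digits = NA)
  rp <- stage_dir("report")
  for (metric in names(result$clusters))
    for (eff in names(result$clusters[[metric]]))
      utils::write.table(result$clusters[[metric]][[eff]]$table,
                         file.path(rp, paste0(metric, "_", eff,
                                              "_clusters.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$correlations,
                     file.path(rp, "correlations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  prov <- list(package = "bandalff",
               version = as.character(utils::packageVersion("bandalff")),
               timestamp = format(Sys.time(), tz = "UTC"),
               config = result$config,
               n_retained = length(result$retained),
               alphasim_threshold_voxels = result$alphasim$threshold_voxels)
  jsonlite::write_json(prov, file.path(out_dir, "derivatives",
                                       "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
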