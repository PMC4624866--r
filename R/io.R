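#' BOLD run container
#'
#' One subject's 4D time series: `data` is an (x, y, z, time) array in
#' arbitrary signal units, `tr` the sampling interval in seconds, and `grid`
#' the voxel grid (dimensions, voxel sizes in mm, origin in mm).  Voxel
#' indices are 0-based in all reports; mm coordinates are
#' `origin + index * voxel_size`.
#'
#' @param data 4D numeric array.
#' @param tr repetition time in seconds.
#' @param voxel_size_mm voxel edge lengths, scalar or length 3.
#' @param origin_mm world coordinates of voxel (0,0,0), length 3.
#' @return object of class `bold_run`.
#' @export
bold_run <- function(data, tr, voxel_size_mm = 3, origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop_domain("data must be a 4D (x, y, z, time) array")
  if (dim(data)[4L] < 8L) stop_domain("need at least 8 timepoints")
  if (!is.finite(tr) || tr <= 0) stop_domain("tr must be positive")
  vs <- rep_len(voxel_size_mm, 3L)
  if (any(vs <= 0)) stop_domain("voxel sizes must be positive")
  structure(list(data = data, tr = tr,
                 grid = volume_grid(dim(data)[1:3], vs, origin_mm)),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %d x %d x %d voxels x %d volumes, TR = %g s, voxel %s mm\n",
              d[1], d[2], d[3], d[4], x$tr,
              paste(x$grid$voxel_size_mm, collapse = "x")))
  invisible(x)
}

#' Voxel grid metadata
#' @param dims integer grid dimensions, length 3.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param origin_mm world coordinates of voxel (0,0,0).
#' @return list of class `volume_grid`.
#' @export
volume_grid <- function(dims, voxel_size_mm = 3, origin_mm = c(0, 0, 0)) {
  structure(list(dims = as.integer(dims),
                 voxel_size_mm = rep_len(voxel_size_mm, 3L),
                 origin_mm = rep_len(origin_mm, 3L)),
            class = "volume_grid")
}

#' Voxel volume of a grid, in cubic millimetres
#' @param grid a [volume_grid()].
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$voxel_size_mm)

run_affine <- function(grid) {
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(grid$voxel_size_mm)
  aff[1:3, 4] <- grid$origin_mm
  aff
}

#' Read / write BOLD runs and 3D maps as NIfTI-1
#'
#' `write_bold_nifti()` stores a run as a 4D NIfTI-1 file (float32, voxel
#' sizes and TR in `pixdim`, origin in the sform); `read_bold_nifti()` reads
#' it back.  The round trip preserves grid metadata exactly and values to
#' float32 precision.  `write_map_nifti()`/`read_map_nifti()` do the same for
#' a single 3D map (e.g. an ALFF or t map); `NA` is stored as NaN.
#'
#' @param run a [bold_run()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_bold_nifti()` returns a `bold_run`.
#' @export
write_bold_nifti <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  img <- RNifti::asNifti(run$data)
  img <- RNifti::`sform<-`(img, structure(run_affine(run$grid), code = 2L))
  attr(img, "pixdim") <- c(run$grid$voxel_size_mm, run$tr)
  attr(img, "pixunits") <- c("mm", "s")
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop_domain("expected a 4D NIfTI file, got ", length(d), "D: ", path)
  pd <- attr(img, "pixdim")
  aff <- RNifti::xform(img)
  bold_run(array(as.numeric(img), dim = d), tr = pd[4L],
           voxel_size_mm = abs(pd[1:3]), origin_mm = aff[1:3, 4L])
}

#' @rdname write_bold_nifti
#' @param map 3D numeric array matching `grid`.
#' @param grid a [volume_grid()].
#' @export
write_map_nifti <- function(map, grid, path) {
  if (!is.array(map) || length(dim(map)) != 3L)
    stop_domain("map must be a 3D array")
  if (!all(dim(map) == grid$dims)) stop_domain("map does not match grid")
  img <- RNifti::asNifti(array(as.numeric(map), dim = dim(map)))
  img <- RNifti::`sform<-`(img, structure(run_affine(grid), code = 2L))
  attr(img, "pixdim") <- grid$voxel_size_mm
  attr(img, "pixunits") <- c("mm", "s")
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop_domain("expected a 3D NIfTI file, got ", length(d), "D: ", path)
  list(map = array(as.numeric(img), dim = d),
       grid = volume_grid(d, abs(attr(img, "pixdim")[1:3]),
                          RNifti::xform(img)[1:3, 4L]))
}

#' Motion trace container and plain-text I/O
#'
#' A motion trace holds the six rigid-body realignment parameters per
#' retained volume: three translations in mm and three rotations in degrees.
#' The text format is the conventional 6-column whitespace-delimited table,
#' one row per volume.
#'
#' @param translations_mm T x 3 matrix of translations (mm).
#' @param rotations_deg T x 3 matrix of rotations (degrees).
#' @return object of class `motion_trace`.
#' @export
motion_trace <- function(translations_mm, rotations_deg) {
  translations_mm <- as.matrix(translations_mm)
  rotations_deg <- as.matrix(rotations_deg)
  stopifnot(ncol(translations_mm) == 3L, ncol(rotations_deg) == 3L,
            nrow(translations_mm) == nrow(rotations_deg))
  if (nrow(translations_mm) == 0L) stop_domain("empty motion trace")
  if (any(!is.finite(translations_mm)) || any(!is.finite(rotations_deg)))
    stop_domain("motion trace contains non-finite values")
  structure(list(translations_mm = translations_mm,
                 rotations_deg = rotations_deg),
            class = "motion_trace")
}

#' @rdname motion_trace
#' @param trace a `motion_trace`.
#' @param path file path.
#' @export
write_motion_text <- function(trace, path) {
  stopifnot(inherits(trace, "motion_trace"))
  m <- cbind(trace$translations_mm, trace$rotations_deg)
  utils::write.table(format(m, digits = 10, scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname motion_trace
#' @export
read_motion_text <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L) stop_domain("motion file must have 6 columns: ", path)
  motion_trace(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE])
}

#' Phenotype table I/O (TSV)
#'
#' Columns: `subject_id`, `group` (1 = patient, 2 = control), `age` (years),
#' `sex` (0/1), `education_years`, `thq` (Tinnitus Handicap Questionnaire
#' score, 0-100), `duration_months` (tinnitus duration; `NA` for controls).
#'
#' @param pheno data.frame with the columns above.
#' @param path file path.
#' @export
write_pheno_tsv <- function(pheno, path) {
  need <- c("subject_id", "group", "age", "sex", "education_years",
            "thq", "duration_months")
  if (!all(need %in% names(pheno)))
    stop_domain("phenotype table is missing columns: ",
                paste(setdiff(need, names(pheno)), collapse = ", "))
  utils::write.table(pheno[need], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_pheno_tsv
#' @export
read_pheno_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
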