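#' Discard initial volumes of a run
#'
#' Drops the first `n_discard` volumes, the standard allowance for signal
#' equilibration and subject adaptation at the start of a resting-state scan
#' (240 acquired volumes minus 10 leaves the 230 analysed here by default).
#'
#' @param run a [bold_run()].
#' @param n_discard number of leading volumes to drop (default 10).
#' @return a `bold_run` shortened by `n_discard` volumes; values unchanged.
#' @export
discard_initial_volumes <- function(run, n_discard = 10L) {
  stopifnot(inherits(run, "bold_run"))
  n_discard <- as.integer(n_discard)
  nt <- dim(run$data)[4L]
  if (n_discard < 0L) stop_domain("n_discard must be >= 0")
  if (n_discard >= nt)
    stop_domain("cannot discard ", n_discard, " of ", nt, " volumes")
  if (n_discard == 0L) return(run)
  run$data <- run$data[, , , (n_discard + 1L):nt, drop = FALSE]
  run
}

#' Screen a motion trace against exclusion limits
#'
#' A run is excluded iff any single translation parameter exceeds
#' `max_translation_mm` in absolute value, or any rotation parameter exceeds
#' `max_rotation_deg`, at any timepoint.  The rule is a strict `>` relative to
#' the reference volume, so a parameter exactly at the limit keeps the run.
#'
#' @param trace a [motion_trace()].
#' @param max_translation_mm translation limit in mm (default 2.0).
#' @param max_rotation_deg rotation limit in degrees (default 2.0).
#' @return list with `decision` (`"keep"` or `"exclude"`) and, when excluded,
#'   the offending `parameter` (`"translation"`/`"rotation"`), `axis` (1-3),
#'   `timepoint` and `value`.
#' @export
screen_motion <- function(trace, max_translation_mm = 2.0,
                          max_rotation_deg = 2.0) {
  stopifnot(inherits(trace, "motion_trace"))
  for (what in c("translation", "rotation")) {
    m <- if (what == "translation") trace$translations_mm else trace$rotations_deg
    lim <- if (what == "translation") max_translation_mm else max_rotation_deg
    over <- which(abs(m) > lim, arr.ind = TRUE)
    if (nrow(over) > 0L) {
      i <- over[which.max(abs(m[over])), , drop = TRUE]
      return(list(decision = "exclude", parameter = what,
                  axis = unname(i[2L]), timepoint = unname(i[1L]),
                  value = m[i[1L], i[2L]]))
    }
  }
  list(decision = "keep")
}

#' Screen every subject of a cohort
#'
#' @param motions list of [motion_trace()]s.
#' @inheritParams screen_motion
#' @return logical vector, `TRUE` for retained subjects.
#' @export
screen_cohort_motion <- function(motions, max_translation_mm = 2.0,
                                 max_rotation_deg = 2.0) {
  vapply(motions, function(tr)
    screen_motion(tr, max_translation_mm, max_rotation_deg)$decision == "keep",
    logical(1L))
}
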