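#' Frequency band definition
#'
#' A named half-open frequency interval `[f_low, f_high)` in Hz.  The
#' uppermost canonical band (slow-2) is closed at the Nyquist frequency so
#' that the five canonical bands partition the detectable range `(0, 0.25]` Hz
#' at TR = 2 s with no gaps or overlaps.
#'
#' @param name band label, e.g. `"slow-4"`.
#' @param f_low lower edge in Hz (inclusive).
#' @param f_high upper edge in Hz (exclusive, unless `closed_upper`).
#' @param closed_upper if `TRUE` the upper edge is included (used for the
#'   band that ends at Nyquist).
#' @return an object of class `frequency_band`.
#' @export
frequency_band <- function(name, f_low, f_high, closed_upper = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(f_low) || !is.finite(f_high) || f_low < 0 || f_low >= f_high)
    stop_domain("invalid band: need 0 <= f_low < f_high")
  structure(list(name = name, f_low = f_low, f_high = f_high,
                 closed_upper = isTRUE(closed_upper)),
            class = "frequency_band")
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<frequency_band> %s: [%g, %g%s Hz\n", x$name, x$f_low, x$f_high,
              if (x$closed_upper) "]" else ")"))
  invisible(x)
}

#' Canonical slow-6 ... slow-2 frequency bands
#'
#' The five canonical sub-bands of the BOLD low-frequency range at TR = 2 s:
#' slow-6 \[0, 0.01), slow-5 \[0.01, 0.027), slow-4 \[0.027, 0.073),
#' slow-3 \[0.073, 0.198) and slow-2 \[0.198, 0.25\] Hz.  Under the half-open
#' convention (boundary frequencies belong to the higher band; 0.027 Hz is
#' slow-4) the bands partition `(0, 0.25]` exactly.
#'
#' @return a named list of five [frequency_band] objects, slow-6 first.
#' @export
standard_bands <- function() {
  b <- list(
    frequency_band("slow-6", 0.000, 0.010),
    frequency_band("slow-5", 0.010, 0.027),
    frequency_band("slow-4", 0.027, 0.073),
    frequency_band("slow-3", 0.073, 0.198),
    frequency_band("slow-2", 0.198, 0.250, closed_upper = TRUE)
  )
  names(b) <- vapply(b, `[[`, "", "name")
  b
}

#' Which frequency bins fall inside a band
#'
#' Bin membership is decided by bin-centre frequency: `f_low <= f < f_high`
#' (or `<= f_high` for a band closed at its upper edge), always excluding the
#' DC bin (`f = 0`).  Comparisons carry a 1e-12 Hz guard so that a bin centre
#' that equals a band edge up to floating-point rounding lands on the correct
#' side.
#'
#' @param frequencies numeric vector of bin-centre frequencies in Hz.
#' @param band a [frequency_band].
#' @return logical vector, `TRUE` for bins inside the band.
#' @export
band_bin_mask <- function(frequencies, band) {
  tol <- 1e-12
  upper <- if (band$closed_upper) frequencies <= band$f_high + tol
           else                   frequencies <  band$f_high - tol
  frequencies >= band$f_low - tol & upper & frequencies > tol
}
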