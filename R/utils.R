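#' Derive a reproducible sub-stream seed
#'
#' All randomness in a pipeline run flows from one master seed; named
#' sub-streams (one per stage, one per subject) are derived deterministically
#' so that stages can be re-run independently without replaying the whole
#' random sequence.
#'
#' @param master integer master seed.
#' @param name character label of the sub-stream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% 2147483161
  as.integer((abs(master) %% 2147483161 * 7919 + h) %% 2147483161)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)
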