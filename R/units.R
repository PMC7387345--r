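#' Convert hours to internal model time (seconds)
#'
#' All rate constants in the reaction network are per-second (transcription
#' rates are quoted in mRNA/s), while every user-facing interface works in
#' hours. This pair of helpers is the only place the conversion lives.
#'
#' @param h time in hours.
#' @return time in seconds.
#' @export
hours_to_seconds <- function(h) {
  stopifnot(is.numeric(h))
  h * 3600
}

#' @rdname hours_to_seconds
#' @param s time in seconds.
#' @return time in hours.
#' @export
seconds_to_hours <- function(s) {
  stopifnot(is.numeric(s))
  s / 3600
}
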