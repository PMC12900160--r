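#' Construct a single-channel physiological trace
#'
#' A `psg_trace` is the basic container moved between the simulator, the I/O
#' layer and the preprocessing stages: one uniformly sampled channel of one
#' patient's overnight recording.
#'
#' @param patient_id Opaque patient identifier (character scalar).
#' @param channel Channel name, one of `"SpO2"` (percent saturation) or
#'   `"FP0"` (nasal airflow, arbitrary units).
#' @param rate Sampling rate in Hz (> 0).
#' @param samples Numeric vector of samples. `NA` marks masked samples.
#' @param start_offset Offset of the first sample from record start, seconds.
#' @return An object of class `psg_trace`.
#' @export
psg_trace <- function(patient_id, channel, rate, samples, start_offset = 0) {
  channel <- match.arg(channel, c("SpO2", "FP0"))
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number")
  if (length(samples) == 0L)
    stop("`samples` must be non-empty")
  structure(
    list(
      patient_id = as.character(patient_id),
      channel = channel,
      rate = as.numeric(rate),
      samples = as.numeric(samples),
      start_offset = as.numeric(start_offset)
    ),
    class = "psg_trace"
  )
}

#' @export
print.psg_trace <- function(x, ...) {
  cat(sprintf(
    "<psg_trace> patient %s, channel %s, %d samples @ %g Hz (%.1f s)\n",
    x$patient_id, x$channel, length(x$samples), x$rate,
    length(x$samples) / x$rate
  ))
  invisible(x)
}

#' Time stamps of the samples of a trace
#'
#' @param trace A `psg_trace`.
#' @return Numeric vector of sample times in seconds from record start.
#' @export
trace_times <- function(trace) {
  trace$start_offset + (seq_along(trace$samples) - 1L) / trace$rate
}

#' Duration of a trace in seconds
#' @param trace A `psg_trace`.
#' @return Duration in seconds (n samples / rate).
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$rate

stopifnot_trace <- function(trace) {
  if (!inherits(trace, "psg_trace")) stop("expected a `psg_trace` object")
  invisible(trace)
}
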