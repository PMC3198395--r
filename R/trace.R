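#' Uniformly sampled signal trace
#'
#' Container for a 1-D uniformly sampled signal: whole-cell current (pA),
#' integrated field potential (a.u.) or a dF/F0 time series.
#'
#' @param values numeric vector of samples.
#' @param sample_rate sampling rate, Hz.
#' @param t0 time of the first sample, s.
#' @param units unit label ("pA", "a.u.", "dFF0").
#' @param v_hold holding potential, mV, when the trace is a voltage-clamp
#'   current; NA otherwise.
#' @return an object of class `glia_trace`.
#' @export
glia_trace <- function(values, sample_rate, t0 = 0, units = "a.u.",
                       v_hold = NA_real_) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  if (!all(is.finite(values))) stop("trace values must be finite")
  structure(list(values = as.numeric(values), sample_rate = sample_rate,
                 t0 = t0, units = units, v_hold = v_hold),
            class = "glia_trace")
}

#' @export
print.glia_trace <- function(x, ...) {
  cat(sprintf("<glia_trace> %d samples @ %g Hz (%.1f s), units %s%s\n",
              length(x$values), x$sample_rate,
              length(x$values) / x$sample_rate, x$units,
              if (is.finite(x$v_hold)) sprintf(", V_hold %g mV", x$v_hold)
              else ""))
  invisible(x)
}

#' Time axis of a trace
#' @param x a `glia_trace`.
#' @return numeric vector of sample times, s.
#' @export
trace_times <- function(x) {
  x$t0 + (seq_along(x$values) - 1L) / x$sample_rate
}

#' Burst train: detected or ground-truth population-burst peaks
#'
#' @param peak_times strictly increasing peak times, s.
#' @param amplitude per-burst amplitude above local baseline (a.u.).
#' @param half_width per-burst duration at half-maximal amplitude, s.
#' @param duration duration of the parent recording, s.
#' @return an object of class `burst_train`.
#' @export
burst_train <- function(peak_times, amplitude = rep(NA_real_, length(peak_times)),
                        half_width = rep(NA_real_, length(peak_times)),
                        duration = NA_real_) {
  if (length(peak_times) > 1L && any(diff(peak_times) <= 0))
    stop("peak_times must be strictly increasing")
  ok <- is.finite(half_width)
  if (any(ok) && any(half_width[ok] <= 0))
    stop("half_width must be > 0 where defined")
  structure(list(peak_times = as.numeric(peak_times),
                 amplitude = as.numeric(amplitude),
                 half_width = as.numeric(half_width),
                 duration = duration),
            class = "burst_train")
}

#' @export
print.burst_train <- function(x, ...) {
  cat(sprintf("<burst_train> %d bursts over %s s\n", length(x$peak_times),
              format(x$duration)))
  invisible(x)
}
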