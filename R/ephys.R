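# Electrophysiology analysis: integrated field potentials, burst
# detection, cycle-triggered averaging of whole-cell currents, rhythmic
# current quantification, IV analysis and input resistance.

#' Band-pass filter, rectify and integrate an extracellular recording
#'
#' Mirrors the analog signal chain of an extracellular amplifier: the raw
#' field potential is band-pass filtered (default 0.5-2.5 kHz), full-wave
#' rectified, and passed through a leaky integrator with time constant
#' `tau`. The output (the "integrated field potential") is non-negative
#' and its peaks mark population bursts.
#'
#' @param raw a [glia_trace()] of the raw extracellular voltage.
#' @param band band-pass corner frequencies, Hz (length 2, within
#'   Nyquist).
#' @param tau leaky-integrator time constant, s.
#' @return a [glia_trace()] of the integrated signal (a.u.).
#' @export
integrate_field_potential <- function(raw, band = c(500, 2500), tau = 0.05) {
  stopifnot(inherits(raw, "glia_trace"))
  nyq <- raw$sample_rate / 2
  if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L] ||
      band[2L] >= nyq)
    stop("band must be increasing, positive and within the Nyquist frequency")
  bf <- signal::butter(2, band / nyq, type = "pass")
  filt <- signal::filtfilt(bf, raw$values)
  rect <- abs(filt)
  # one-pole leaky integrator, gain-normalized so a steady rectified
  # level passes through at unit gain
  alpha <- exp(-1 / (tau * raw$sample_rate))
  integ <- as.numeric(signal::filter(c(1 - alpha), c(1, -alpha), rect))
  glia_trace(integ, raw$sample_rate, t0 = raw$t0, units = "a.u.")
}

# robust SD: 1.4826 * median absolute deviation
robust_sd <- function(x) stats::mad(x, constant = 1.4826)

# centered boxcar smoother (odd width, edges replicated); width_s <= 0
# disables smoothing
smooth_boxcar <- function(x, width_s, sample_rate) {
  n <- round(width_s * sample_rate)
  if (n <= 1L) return(x)
  n <- 2L * (n %/% 2L) + 1L
  half <- n %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / n, n), sides = 2L))[half +
                                                             seq_along(x)]
}

# local baseline preceding index i: median over `pre_s` seconds
local_baseline <- function(values, i, sample_rate, pre_s = 2) {
  n_pre <- max(1L, round(pre_s * sample_rate))
  j0 <- max(1L, i - n_pre)
  j1 <- max(1L, i - 1L)
  stats::median(values[j0:j1])
}

# width at half of (peak - baseline) with linear interpolation of the
# crossings on either side of the peak; NA if a crossing is not found.
half_width_at <- function(values, i, baseline, sample_rate) {
  half <- baseline + (values[i] - baseline) / 2
  l <- i
  while (l > 1L && values[l] > half) l <- l - 1L
  if (values[l] > half) return(NA_real_)
  r <- i
  n <- length(values)
  while (r < n && values[r] > half) r <- r + 1L
  if (values[r] > half) return(NA_real_)
  tl <- l + (half - values[l]) / (values[l + 1L] - values[l])
  tr <- r - 1 + (half - values[r - 1L]) / (values[r] - values[r - 1L])
  (tr - tl) / sample_rate
}

#' Detect population bursts on an integrated field potential
#'
#' Peaks exceeding `median + threshold_k * robust SD` (robust SD =
#' 1.4826 * MAD) and separated by at least `refractory` are reported,
#' together with the amplitude above a local pre-burst baseline (median
#' of the preceding 2 s) and the duration at half-maximal amplitude.
#'
#' @param integrated a [glia_trace()], e.g. from
#'   [integrate_field_potential()] or [simulate_burst_train()].
#' @param threshold_k detection threshold in robust SDs above the median.
#' @param refractory minimum peak separation, s.
#' @param metric_smooth_s boxcar width, s, of the light smoothing
#'   applied before per-burst metrics (amplitude, half-width) are read
#'   off; suppresses the upward bias that single-sample noise extremes
#'   would otherwise impose on the peak level. Short relative to any
#'   physiological burst (default 0.1 s); 0 disables.
#' @return a [burst_train()]; empty when nothing crosses threshold.
#' @export
detect_bursts <- function(integrated, threshold_k = 4, refractory = 2,
                          metric_smooth_s = 0.1) {
  stopifnot(inherits(integrated, "glia_trace"))
  v <- integrated$values
  sr <- integrated$sample_rate
  if (length(v) <= refractory * sr)
    stop("trace shorter than the refractory period")
  # robust threshold; the 5 %-of-range floor keeps a noise-free trace
  # (MAD = 0) from yielding a degenerate zero-height threshold
  med <- stats::median(v)
  thr <- med + max(threshold_k * robust_sd(v), 0.05 * (max(v) - med))
  n <- length(v)
  # one candidate per contiguous supra-threshold run: local maxima on a
  # decaying tail that never dips below threshold are not new bursts
  above <- v > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  cand <- vapply(runs, function(j)
    as.integer(starts[j] + which.max(v[starts[j]:ends[j]]) - 1L),
    integer(1))
  if (length(cand) == 0L)
    return(burst_train(numeric(0), duration = n / sr))
  # greedy refractory enforcement, largest peaks first
  cand <- cand[order(v[cand], decreasing = TRUE)]
  keep <- integer(0)
  min_gap <- refractory * sr
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  # metrics on a lightly smoothed copy; peak index refined locally
  vs <- smooth_boxcar(v, metric_smooth_s, sr)
  half_win <- max(1L, round(metric_smooth_s * sr))
  keep <- vapply(keep, function(i) {
    j0 <- max(1L, i - half_win); j1 <- min(n, i + half_win)
    as.integer(j0 + which.max(vs[j0:j1]) - 1L)
  }, integer(1))
  keep <- unique(keep)
  base <- vapply(keep, function(i) local_baseline(vs, i, sr), numeric(1))
  amp <- vs[keep] - base
  hw <- vapply(seq_along(keep), function(j)
    half_width_at(vs, keep[j], base[j], sr), numeric(1))
  burst_train(integrated$t0 + (keep - 1L) / sr, amplitude = amp,
              half_width = hw, duration = n / sr)
}

#' Summary metrics of a burst train
#'
#' @param train a [burst_train()].
#' @param duration recording duration, s; defaults to the train's.
#' @return list: `frequency` (Hz, count/duration), `mean_amplitude`,
#'   `mean_half_width` (s), `n_bursts`, and `defined` (FALSE when the
#'   train is empty, in which case amplitude and half-width are NA).
#' @export
burst_metrics <- function(train, duration = NULL) {
  stopifnot(inherits(train, "burst_train"))
  if (is.null(duration)) duration <- train$duration
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  n <- length(train$peak_times)
  if (n == 0L)
    return(list(frequency = 0, mean_amplitude = NA_real_,
                mean_half_width = NA_real_, n_bursts = 0L, defined = FALSE))
  list(frequency = n / duration,
       mean_amplitude = mean(train$amplitude, na.rm = TRUE),
       mean_half_width = mean(train$half_width, na.rm = TRUE),
       n_bursts = n, defined = TRUE)
}

#' Cycle-triggered average of a whole-cell current
#'
#' Aligns the current on detected population-burst peaks and averages the
#' aligned segments sample-wise, pulling small phase-locked components
#' out of the recording noise. Segments are taken from `window[1]` to
#' `window[2]` around each trigger (default 5 s before to 15 s after the
#' peak); triggers whose windows do not lie fully inside the trace are
#' dropped, and at least `min_cycles` complete cycles (default 6) are
#' required.
#'
#' @param current a [glia_trace()] of the whole-cell current (pA).
#' @param triggers a [burst_train()] or numeric vector of trigger
#'   times, s.
#' @param window relative averaging window, s (length 2).
#' @param min_cycles minimum number of usable cycles.
#' @return an object of class `cycle_average`: `rel_time` (s),
#'   `mean_values`, `n_cycles`, `sample_rate`, `baseline_window`,
#'   `response_window` (defaults used by [measure_iresp()]).
#' @export
cta_current <- function(current, triggers, window = c(-5, 15),
                        min_cycles = 6L) {
  stopifnot(inherits(current, "glia_trace"))
  tt <- if (inherits(triggers, "burst_train")) triggers$peak_times
        else as.numeric(triggers)
  sr <- current$sample_rate
  n <- length(current$values)
  i_pre <- round(window[1L] * sr)
  i_post <- round(window[2L] * sr)
  centers <- round((tt - current$t0) * sr) + 1L
  ok <- centers + i_pre >= 1L & centers + i_post <= n
  centers <- centers[ok]
  if (length(centers) < min_cycles)
    stop(sprintf(
      "insufficient cycles: %d usable triggers, %d required",
      length(centers), min_cycles))
  rel_idx <- i_pre:i_post
  seg <- vapply(centers, function(c0) current$values[c0 + rel_idx],
                numeric(length(rel_idx)))
  structure(list(rel_time = rel_idx / sr,
                 mean_values = rowMeans(seg),
                 n_cycles = length(centers), sample_rate = sr,
                 baseline_window = c(-5, -1),
                 response_window = c(-0.5, 2)),
            class = "cycle_average")
}

#' @export
print.cycle_average <- function(x, ...) {
  cat(sprintf("<cycle_average> %d cycles, window [%g, %g] s\n",
              x$n_cycles, min(x$rel_time), max(x$rel_time)))
  invisible(x)
}

#' Rhythmic-current amplitude from a cycle-triggered average
#'
#' The burst-locked current amplitude (I_resp,A) is read off the averaged
#' trace as the extremum within the response window minus the mean of
#' the baseline window. Inward currents give negative values. Before the
#' extremum is taken the averaged trace is smoothed with a short boxcar
#' (`smooth_s`): the extremum of an unsmoothed noisy average is biased
#' away from baseline by single-sample noise excursions, while the
#' astrocytic current itself evolves over seconds, so a 0.2 s boxcar
#' suppresses the bias at negligible attenuation.
#'
#' @param avg a `cycle_average` from [cta_current()].
#' @param baseline_window,response_window relative-time windows, s;
#'   default to those carried by `avg` ([-5, -1] and [-0.5, +2]).
#' @param smooth_s boxcar width, s (0 disables smoothing).
#' @return signed amplitude in the trace's units (pA for currents).
#' @export
measure_iresp <- function(avg, baseline_window = avg$baseline_window,
                          response_window = avg$response_window,
                          smooth_s = 0.2) {
  stopifnot(inherits(avg, "cycle_average"))
  rt <- avg$rel_time
  for (w in list(baseline_window, response_window)) {
    if (w[1L] < min(rt) - 1e-9 || w[2L] > max(rt) + 1e-9)
      stop("analysis window lies outside the averaged trace")
  }
  vals <- smooth_boxcar(avg$mean_values, smooth_s, avg$sample_rate)
  bi <- rt >= baseline_window[1L] & rt <= baseline_window[2L]
  ri <- rt >= response_window[1L] & rt <= response_window[2L]
  b <- mean(vals[bi])
  resp <- vals[ri]
  resp[which.max(abs(resp - b))] - b
}

#' Normalize a current-voltage relation to its largest current
#'
#' Each amplitude is divided by the maximum absolute amplitude over the
#' range of holding potentials (I/I_max); signs are preserved, so the
#' normalized values lie in [-1, 1] with exactly one of magnitude 1.
#'
#' @param holding_potentials mV.
#' @param amplitudes pA, signed (inward-negative).
#' @return list of class `iv_curve`: `holding_potentials`, `amplitudes`,
#'   `normalized`.
#' @export
normalize_iv <- function(holding_potentials, amplitudes) {
  if (length(holding_potentials) != length(amplitudes))
    stop("holding_potentials and amplitudes must have equal length")
  m <- max(abs(amplitudes))
  if (m == 0) stop("degenerate IV: all amplitudes are zero")
  structure(list(holding_potentials = holding_potentials,
                 amplitudes = amplitudes,
                 normalized = amplitudes / m),
            class = "iv_curve")
}

#' Input resistance from a voltage-step response
#'
#' R_in = delta_V / delta_I from the steady-state current deflection,
#' measured over the last 20 % of the step relative to the pre-step
#' baseline. Units handled explicitly: mV / pA * 1000 = MOhm.
#'
#' @param trace a [glia_trace()] of the current response (pA).
#' @param step_voltage step amplitude relative to holding, mV.
#' @param step_window start/end of the step, s (length 2).
#' @return list: `R_in` (MOhm), `delta_I` (pA), `delta_V` (mV).
#' @export
measure_input_resistance <- function(trace, step_voltage, step_window) {
  delta_i <- steady_state_delta(trace, step_window)
  if (delta_i == 0) stop("unmeasurable: zero steady-state current deflection")
  list(R_in = 1000 * step_voltage / delta_i, delta_I = delta_i,
       delta_V = step_voltage)
}

# steady-state current deflection: mean over the last 20 % of the step
# minus the pre-step baseline mean
steady_state_delta <- function(trace, step_window) {
  stopifnot(inherits(trace, "glia_trace"))
  tt <- trace_times(trace)
  tol <- 0.25 / trace$sample_rate   # guard against float drift at window edges
  pre <- trace$values[tt < step_window[1L] - tol]
  in_step <- tt >= step_window[1L] - tol & tt < step_window[2L] - tol
  vs <- trace$values[in_step]
  if (!length(pre) || !length(vs)) stop("step_window outside the trace")
  ss <- vs[seq.int(ceiling(0.8 * length(vs)) + 1L, length(vs))]
  mean(ss) - mean(pre)
}

#' Input resistance and linearity from a full step protocol
#'
#' Fits delta_I against delta_V across all steps by least squares;
#' R_in is 1000/slope (MOhm) and the r-squared of the fit quantifies
#' IV linearity.
#'
#' @param protocol a `step_protocol` from [simulate_step_protocol()], or
#'   a list with `step_voltages`, `traces`, `step_window`.
#' @return list of class `step_result`: `step_voltages`,
#'   `steady_state_deltas` (pA), `R_in` (MOhm), `linearity_r2`.
#' @export
analyze_step_protocol <- function(protocol) {
  dv <- protocol$step_voltages
  di <- vapply(seq_along(dv), function(i)
    steady_state_delta(protocol$traces[[i]], protocol$step_window),
    numeric(1))
  fit <- stats::lm(di ~ dv)
  slope <- stats::coef(fit)[["dv"]]
  r2 <- r_squared(fit, di)
  if (slope == 0) stop("unmeasurable: zero IV slope")
  structure(list(step_voltages = dv, steady_state_deltas = di,
                 R_in = 1000 / slope, linearity_r2 = r2),
            class = "step_result")
}

#' Classify a cell as passive from its current-voltage relation
#'
#' Passive astrocytes are distinguished by a linear IV relation; a least
#' squares line is fitted and the cell called passive when r-squared is
#' at or above `r2_min`.
#'
#' @param voltages mV (at least 3 distinct values).
#' @param currents pA.
#' @param r2_min linearity threshold (default 0.98).
#' @return list: `passive` (logical), `r2`, `slope` (pA/mV).
#' @export
classify_passive <- function(voltages, currents, r2_min = 0.98) {
  if (length(voltages) != length(currents))
    stop("voltages and currents must have equal length")
  if (length(unique(voltages)) < 3L)
    stop("at least 3 distinct voltages required")
  fit <- stats::lm(currents ~ voltages)
  r2 <- r_squared(fit, currents)
  list(passive = r2 >= r2_min, r2 = r2,
       slope = stats::coef(fit)[["voltages"]])
}

# r-squared computed directly (summary.lm warns on perfect fits)
r_squared <- function(fit, y) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / sst
}
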