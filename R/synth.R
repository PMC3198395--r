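# Synthetic electrophysiology and imaging generator.
#
# The generator encodes the biophysical picture the analysis is built to
# test: a passive astrocyte whose voltage-clamp current tracks shifts of
# the potassium equilibrium potential driven by burst-locked rises of
# extracellular K+, plus an electrogenic glutamate-transporter current
# with the same time course. Every simulation is fully determined by an
# explicit seed and returns a ground-truth manifest.

GAS_CONSTANT <- 8.314462618   # J / (mol K)
FARADAY <- 96485.33212        # C / mol

#' Potassium Nernst potential
#'
#' @param K_out,K_in extracellular / intracellular potassium, mM.
#' @param temperature absolute temperature, K.
#' @return equilibrium potential, mV.
#' @export
nernst_potential <- function(K_out, K_in, temperature = 303) {
  1000 * GAS_CONSTANT * temperature / FARADAY * log(K_out / K_in)
}

# Log-normal burst envelope with unit peak and exact FWHM.
# Shape parameter s fixed at 0.3 gives a mildly asymmetric burst (fast
# rise, slower decay); the peak time is solved so the width at half
# maximum equals `fwhm` exactly.
lognormal_envelope <- function(t_rel, fwhm, shape = 0.3) {
  a <- shape * sqrt(2 * log(2))
  t_peak <- fwhm / (2 * sinh(a))
  out <- numeric(length(t_rel))
  # envelope peak sits at t_rel = 0
  tt <- t_rel + t_peak
  pos <- tt > 0
  out[pos] <- exp(-(log(tt[pos] / t_peak))^2 / (2 * shape^2))
  out
}

# Burst-locked concentration/transporter kernel: difference of
# exponentials with rise tau/8, decay tau, normalized to unit peak at the
# burst peak time (t_rel = 0).
burst_kernel <- function(t_rel, tau) {
  tau_r <- tau / 8
  t_star <- log(tau / tau_r) * tau_r * tau / (tau - tau_r)
  norm <- exp(-t_star / tau) - exp(-t_star / tau_r)
  u <- t_rel + t_star
  out <- numeric(length(t_rel))
  pos <- u > 0
  out[pos] <- (exp(-u[pos] / tau) - exp(-u[pos] / tau_r)) / norm
  out
}

# Render sum of per-burst kernels on a time grid. kernel_fun(t_rel) must
# vanish for t_rel well before 0.
render_bursts <- function(times, burst_times, kernel_fun, support = c(-10, 60)) {
  out <- numeric(length(times))
  if (length(burst_times) == 0L) return(out)
  dt <- times[2L] - times[1L]
  for (tb in burst_times) {
    i0 <- max(1L, floor((tb + support[1L] - times[1L]) / dt) + 1L)
    i1 <- min(length(times), ceiling((tb + support[2L] - times[1L]) / dt) + 1L)
    if (i1 < i0) next
    idx <- i0:i1
    out[idx] <- out[idx] + kernel_fun(times[idx] - tb)
  }
  out
}

#' Simulate a rhythmic population-burst train and its integrated field
#' potential
#'
#' Inter-burst intervals are drawn from a gamma distribution with mean
#' `1/burst_rate` and coefficient of variation `rate_jitter_cv`
#' (degenerate at zero jitter: a perfectly regular rhythm). Each burst is
#' rendered as a smooth unimodal log-normal envelope with the configured
#' full width at half maximum, and Gaussian noise is added. The first
#' burst is centred half an interval into the recording.
#'
#' @param p a [network_params()] object.
#' @return a list with `bursts` (a [burst_train()] of ground-truth peak
#'   times) and `trace` (the rendered integrated field potential as a
#'   [glia_trace()]).
#' @export
simulate_burst_train <- function(p) {
  stopifnot(inherits(p, "network_params"))
  n_samp <- round(p$duration * p$sample_rate)
  times <- (seq_len(n_samp) - 1L) / p$sample_rate
  peak_times <- numeric(0)
  if (p$burst_rate > 0) {
    mean_iv <- 1 / p$burst_rate
    n_draw <- ceiling(p$duration / mean_iv * (1 + 4 * p$rate_jitter_cv) + 10)
    peak_times <- with_seed(p$seed, {
      if (p$rate_jitter_cv == 0) {
        iv <- rep(mean_iv, n_draw)
      } else {
        shp <- 1 / p$rate_jitter_cv^2
        iv <- stats::rgamma(n_draw, shape = shp, scale = mean_iv / shp)
      }
      tt <- cumsum(c(mean_iv / 2, iv[-1L]))
      tt[tt < p$duration]
    })
  }
  noise <- with_seed(substream_seed(p$seed, 1L),
                     stats::rnorm(n_samp, 0, p$noise_sd))
  env <- render_bursts(times, peak_times,
                       function(tr) p$burst_amplitude *
                         lognormal_envelope(tr, p$burst_half_width),
                       support = c(-3 * p$burst_half_width,
                                   8 * p$burst_half_width))
  list(bursts = burst_train(peak_times,
                            amplitude = rep(p$burst_amplitude,
                                            length(peak_times)),
                            half_width = rep(p$burst_half_width,
                                             length(peak_times)),
                            duration = p$duration),
       trace = glia_trace(env + noise, p$sample_rate, units = "a.u."))
}

#' Simulate the whole-cell current of a passive astrocyte under voltage
#' clamp
#'
#' The current is the sum of (i) an ohmic potassium component
#' `barium_factor * (V_hold - E_K(t)) / R_m` in which the Nernst
#' potential `E_K(t)` follows burst-locked rises of extracellular
#' potassium `K_out(t) = K_out_base + delta_K * k(t)`, (ii) a glutamate
#' transporter current `glt_factor * glt_amp * k(t)`, and (iii) Gaussian
#' noise. The shared kernel `k(t)` rises fast and decays with
#' `kernel_tau`, unit peak at the burst peak. Currents are
#' inward-negative; with `V_hold` above `E_K` the standing component is a
#' positive (outward) holding current and the burst-locked component is
#' inward.
#'
#' @param bursts a [burst_train()] of trigger times.
#' @param a an [astro_params()] object.
#' @param sample_rate output sampling rate, Hz.
#' @param duration trace duration, s; defaults to the burst train's.
#' @param seed integer seed for the noise stream.
#' @return a list with `trace` (a [glia_trace()] in pA, `v_hold` set) and
#'   `ground_truth` (list: `burst_times`, `amp_k`, `amp_glt`, `amplitude`
#'   = the analytic noise-free burst-locked peak amplitude in pA,
#'   inward-negative, and `baseline_pA`).
#' @export
simulate_astrocyte_current <- function(bursts, a, sample_rate = 500,
                                       duration = NULL, seed = 1L) {
  stopifnot(inherits(bursts, "burst_train"), inherits(a, "astro_params"))
  if (is.null(duration)) duration <- bursts$duration
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be positive (or supplied via the burst train)")
  if (length(bursts$peak_times) &&
      any(bursts$peak_times < 0 | bursts$peak_times > duration))
    stop("burst times must lie within the trace duration")
  n_samp <- round(duration * sample_rate)
  times <- (seq_len(n_samp) - 1L) / sample_rate
  k <- render_bursts(times, bursts$peak_times,
                     function(tr) burst_kernel(tr, a$kernel_tau),
                     support = c(-2 * a$kernel_tau, 12 * a$kernel_tau))
  K_out <- a$K_out_base + a$delta_K * k
  e_k <- nernst_potential(K_out, a$K_in, a$temperature)
  i_k <- a$barium_factor * 1000 * (a$V_hold - e_k) / a$R_m    # pA
  i_glt <- a$glt_factor * a$glt_amp * k
  noise <- with_seed(seed, stats::rnorm(n_samp, 0, a$noise_sd))
  e_k0 <- nernst_potential(a$K_out_base, a$K_in, a$temperature)
  e_k1 <- nernst_potential(a$K_out_base + a$delta_K, a$K_in, a$temperature)
  amp_k <- -a$barium_factor * 1000 * (e_k1 - e_k0) / a$R_m
  amp_glt <- a$glt_factor * a$glt_amp
  list(trace = glia_trace(i_k + i_glt + noise, sample_rate, units = "pA",
                          v_hold = a$V_hold),
       ground_truth = list(burst_times = bursts$peak_times,
                           amp_k = amp_k, amp_glt = amp_glt,
                           amplitude = amp_k + amp_glt,
                           baseline_pA = a$barium_factor * 1000 *
                             (a$V_hold - e_k0) / a$R_m))
}

#' Peak potassium rise producing a given burst-locked current amplitude
#'
#' Inverts the Nernst relation: returns the `delta_K` (mM) for which the
#' potassium-shift component of [simulate_astrocyte_current()] peaks at
#' `amplitude_pA` (inward-negative) with `barium_factor = 1`.
#'
#' @param amplitude_pA target burst-locked amplitude, pA (sign ignored).
#' @param a an [astro_params()] object supplying `R_m`, `K_out_base`,
#'   `temperature`.
#' @return `delta_K` in mM.
#' @export
delta_k_for_amplitude <- function(amplitude_pA, a) {
  stopifnot(inherits(a, "astro_params"))
  rtf <- 1000 * GAS_CONSTANT * a$temperature / FARADAY
  a$K_out_base * (exp(abs(amplitude_pA) * a$R_m / (1000 * rtf)) - 1)
}

#' Simulate a voltage-step protocol on a passive membrane
#'
#' Ideal passive (ohmic) responses: each step from `V_hold` produces a
#' steady-state current deflection `delta_I = 1000 * delta_V / R_m` (pA),
#' plus Gaussian noise. The current-voltage relation is linear by
#' construction.
#'
#' @param a an [astro_params()] object (`R_m`, `V_hold`, `noise_sd`).
#' @param steps step potentials relative to `V_hold`, mV.
#' @param step_dur step duration, s.
#' @param baseline_dur pre/post-step baseline duration, s.
#' @param sample_rate Hz.
#' @param seed integer seed for the noise stream.
#' @return list of class `step_protocol`: `step_voltages` (mV),
#'   `traces` (list of [glia_trace()], one per step), `step_window`
#'   (start/end of the step, s), `R_m_true` (MOhm).
#' @export
simulate_step_protocol <- function(a, steps = seq(-80, 100, by = 10),
                                   step_dur = 0.2, baseline_dur = 0.1,
                                   sample_rate = 5000, seed = 1L) {
  stopifnot(inherits(a, "astro_params"))
  if (length(steps) == 0L) stop("steps must be nonempty")
  n_base <- round(baseline_dur * sample_rate)
  n_step <- round(step_dur * sample_rate)
  n_tot <- 2L * n_base + n_step
  i_hold <- 0   # baseline-subtracted holding current
  traces <- with_seed(seed, lapply(steps, function(dv) {
    v <- c(rep(i_hold, n_base),
           rep(i_hold + 1000 * dv / a$R_m, n_step),
           rep(i_hold, n_base))
    glia_trace(v + stats::rnorm(n_tot, 0, a$noise_sd), sample_rate,
               units = "pA", v_hold = a$V_hold)
  }))
  structure(list(step_voltages = steps, traces = traces,
                 step_window = c(baseline_dur, baseline_dur + step_dur),
                 R_m_true = a$R_m),
            class = "step_protocol")
}

#' Simulate a two-channel calcium-imaging stack with ground truth
#'
#' Channel 1 is the static identification fluorescence of astrocytes
#' only (e.g. EGFP); channel 2 the calcium indicator. Rhythmic cells gain
#' a burst-locked transient (peak `transient_amp` as dF/F0,
#' mono-exponential decay `decay_tau`) at every population burst;
#' non-rhythmic cells gain transients at Poisson times with their
#' `spont_rate`. Pixel noise is Gaussian with variance affine in the
#' mean (shot-noise proxy): `sd = sqrt(noise_floor^2 + noise_gain *
#' mean)`.
#'
#' @param bursts a [burst_train()]; its peak times drive rhythmic cells.
#' @param layout a [cell_layout()].
#' @param frame_rate Hz.
#' @param duration recording duration, s; defaults to the burst train's.
#' @param size frame size in pixels, `c(rows, cols)`.
#' @param baseline resting indicator fluorescence inside a soma (a.u.).
#' @param background background fluorescence outside cells (a.u.).
#' @param noise_floor,noise_gain noise model parameters (a.u.).
#' @param seed integer seed.
#' @return list of class `imaging_sim`: `ch1`, `ch2` (arrays T x H x W),
#'   `frame_times` (s), `trigger_times` (s), `pixel_size_um`, `rois`
#'   (list of per-cell pixel index matrices, 1-based (row, col)),
#'   `ground_truth` (the layout with per-cell labels and parameters).
#' @export
simulate_imaging_stack <- function(bursts, layout, frame_rate = 5,
                                   duration = NULL, size = c(64, 64),
                                   baseline = 100, background = 10,
                                   noise_floor = 1, noise_gain = 0.05,
                                   pixel_size_um = 1, seed = 1L) {
  stopifnot(inherits(bursts, "burst_train"), inherits(layout, "cell_layout"))
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  if (is.null(duration)) duration <- bursts$duration
  if (!is.finite(duration) || duration <= 0) stop("duration must be positive")
  H <- size[1L]; W <- size[2L]
  if (any(layout$center_row - layout$radius < 1 |
          layout$center_row + layout$radius > H |
          layout$center_col - layout$radius < 1 |
          layout$center_col + layout$radius > W))
    stop("cells must fit within the frame")
  n_fr <- floor(duration * frame_rate)
  frame_times <- (seq_len(n_fr) - 1L) / frame_rate
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  rois <- lapply(seq_len(nrow(layout)), function(i) {
    inside <- (rows - layout$center_row[i])^2 +
      (cols - layout$center_col[i])^2 <= layout$radius[i]^2
    which(inside, arr.ind = TRUE)
  })
  names(rois) <- layout$id
  # per-cell dF/F0 time course
  event_times <- vector("list", nrow(layout))
  dff <- matrix(0, n_fr, nrow(layout))
  for (i in seq_len(nrow(layout))) {
    if (layout$rhythmic[i]) {
      ev <- bursts$peak_times
    } else if (layout$spont_rate[i] > 0) {
      ev <- with_seed(substream_seed(seed, i), {
        n_ev <- stats::rpois(1L, layout$spont_rate[i] / 60 * duration)
        sort(stats::runif(n_ev, 0, duration))
      })
    } else ev <- numeric(0)
    event_times[[i]] <- ev
    if (length(ev) && layout$transient_amp[i] > 0) {
      dff[, i] <- render_bursts(frame_times, ev, function(tr) {
        out <- numeric(length(tr))
        pos <- tr >= 0
        out[pos] <- layout$transient_amp[i] * exp(-tr[pos] / layout$decay_tau[i])
        out
      }, support = c(0, 10 * layout$decay_tau[i]))
    }
  }
  base2 <- matrix(background, H, W)
  ch1_frame <- matrix(0, H, W)
  for (i in seq_len(nrow(layout))) {
    px <- rois[[i]]
    base2[px] <- baseline
    if (layout$kind[i] == "astrocyte") ch1_frame[px] <- baseline
  }
  ch1 <- array(rep(ch1_frame, each = n_fr), dim = c(n_fr, H, W))
  ch2_mean <- array(rep(base2, each = n_fr), dim = c(n_fr, H, W))
  for (i in seq_len(nrow(layout))) {
    px <- rois[[i]]
    lin <- (px[, 2L] - 1L) * H + px[, 1L]  # linear index into a frame
    for (j in seq_along(lin)) {
      idx <- (lin[j] - 1L) * n_fr + seq_len(n_fr)
      ch2_mean[idx] <- baseline * (1 + dff[, i])
    }
  }
  with_seed(substream_seed(seed, 0L), {
    ch1 <- ch1 + array(stats::rnorm(length(ch1), 0,
                                    sqrt(noise_floor^2 + noise_gain * ch1)),
                       dim = dim(ch1))
    ch2 <- ch2_mean + array(stats::rnorm(length(ch2_mean), 0,
                                         sqrt(noise_floor^2 +
                                                noise_gain * ch2_mean)),
                            dim = dim(ch2_mean))
  })
  structure(list(ch1 = ch1, ch2 = ch2, frame_times = frame_times,
                 trigger_times = bursts$peak_times,
                 pixel_size_um = pixel_size_um, rois = rois,
                 ground_truth = list(layout = layout,
                                     event_times = event_times,
                                     burst_times = bursts$peak_times)),
            class = "imaging_sim")
}
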