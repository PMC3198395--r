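#' Network (population-burst) parameters
#'
#' Parameter set describing the rhythmic population activity of the
#' inspiratory network as seen in the integrated field potential: a train
#' of unimodal bursts at a mean rate with jittered inter-burst intervals.
#'
#' @param burst_rate mean burst rate (Hz). The control preparations burst
#'   at about 0.11 Hz.
#' @param rate_jitter_cv coefficient of variation of the inter-burst
#'   intervals (dimensionless). 0 gives a perfectly regular rhythm.
#' @param burst_half_width full width at half-maximal amplitude of each
#'   burst envelope (s); about 0.8 s in control conditions.
#' @param burst_amplitude peak amplitude of the burst envelope (a.u.).
#' @param duration total recording duration (s).
#' @param sample_rate sampling rate of the rendered trace (Hz).
#' @param noise_sd SD of additive Gaussian noise on the rendered trace (a.u.).
#' @param seed integer seed; identical seed and parameters give identical
#'   output.
#' @return an object of class `network_params`.
#' @export
network_params <- function(burst_rate = 0.11, rate_jitter_cv = 0.2,
                           burst_half_width = 0.79, burst_amplitude = 1,
                           duration = 600, sample_rate = 200,
                           noise_sd = 0.02, seed = 1L) {
  stopifnot(is.numeric(burst_rate), length(burst_rate) == 1L)
  if (burst_rate < 0) stop("burst_rate must be >= 0")
  if (rate_jitter_cv < 0) stop("rate_jitter_cv must be >= 0")
  if (burst_half_width <= 0) stop("burst_half_width must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(burst_rate = burst_rate, rate_jitter_cv = rate_jitter_cv,
                 burst_half_width = burst_half_width,
                 burst_amplitude = burst_amplitude, duration = duration,
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "network_params")
}

#' Passive-astrocyte biophysical parameters
#'
#' Describes the whole-cell current model of a passive astrocyte under
#' voltage clamp: an ohmic membrane whose driving force follows the
#' potassium Nernst potential as extracellular potassium rises with each
#' population burst, plus an electrogenic glutamate-transporter current
#' sharing the same burst-locked time course.
#'
#' @param R_m membrane (input) resistance, MOhm. Passive astrocytes here
#'   are low-resistance cells, tens of MOhm.
#' @param V_hold holding potential, mV (typically -70 mV).
#' @param K_out_base resting extracellular potassium, mM (rhythm is
#'   maintained at 8 mM in the slice preparation).
#' @param K_in intracellular potassium, mM (140 mM default for a
#'   K-gluconate pipette solution after titration).
#' @param delta_K burst-locked peak rise of extracellular potassium, mM
#'   (tens of micromolar to ~1.5 mM reported in the ventral respiratory
#'   column).
#' @param temperature bath temperature, K (303 K ~ 30 C; RT/F = 26.1 mV).
#' @param glt_amp peak transporter current, pA, inward-negative.
#' @param barium_factor scales the Kir-mediated (potassium-shift)
#'   component, in [0, 1]; barium block reduces it below 1.
#' @param glt_factor scales the transporter component, in [0, 1]; DHK or
#'   TFB-TBOA block reduces it below 1.
#' @param noise_sd SD of additive current noise, pA.
#' @param kernel_tau decay time constant of the per-burst potassium /
#'   transporter kernel, s.
#' @return an object of class `astro_params`.
#' @export
astro_params <- function(R_m = 29, V_hold = -70, K_out_base = 8,
                         K_in = 140, delta_K = 0.05, temperature = 303,
                         glt_amp = 0, barium_factor = 1, glt_factor = 1,
                         noise_sd = 10, kernel_tau = 1) {
  if (R_m <= 0) stop("R_m must be > 0")
  if (K_out_base <= 0) stop("K_out_base must be > 0 (non-physical concentration)")
  if (K_in <= 0) stop("K_in must be > 0 (non-physical concentration)")
  if (K_out_base + delta_K <= 0) stop("K_out_base + delta_K must be > 0")
  if (barium_factor < 0 || barium_factor > 1) stop("barium_factor must lie in [0, 1]")
  if (glt_factor < 0 || glt_factor > 1) stop("glt_factor must lie in [0, 1]")
  if (temperature <= 0) stop("temperature must be > 0")
  if (kernel_tau <= 0) stop("kernel_tau must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(R_m = R_m, V_hold = V_hold, K_out_base = K_out_base,
                 K_in = K_in, delta_K = delta_K, temperature = temperature,
                 glt_amp = glt_amp, barium_factor = barium_factor,
                 glt_factor = glt_factor, noise_sd = noise_sd,
                 kernel_tau = kernel_tau),
            class = "astro_params")
}

#' Cell layout for synthetic imaging stacks
#'
#' @param id unique cell identifiers (character or integer).
#' @param kind "neuron" or "astrocyte" per cell.
#' @param center_row,center_col soma center, pixels (1-based, may be
#'   fractional).
#' @param radius soma radius, pixels.
#' @param rhythmic logical: does the cell follow the population rhythm
#'   (burst-locked transients)?
#' @param spont_rate spontaneous (Poisson) transient rate for
#'   non-rhythmic cells, events/min.
#' @param transient_amp calcium transient amplitude, as peak dF/F0.
#' @param decay_tau mono-exponential transient decay, s.
#' @return a `data.frame` of class `cell_layout`, one row per cell.
#' @export
cell_layout <- function(id, kind, center_row, center_col, radius,
                        rhythmic, spont_rate = 0, transient_amp = 0.5,
                        decay_tau = 1) {
  df <- data.frame(id = as.character(id), kind = kind,
                   center_row = center_row, center_col = center_col,
                   radius = radius, rhythmic = rhythmic,
                   spont_rate = spont_rate, transient_amp = transient_amp,
                   decay_tau = decay_tau, stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("cell ids must be unique")
  if (any(df$radius < 0)) stop("radii must be non-negative")
  if (!all(df$kind %in% c("neuron", "astrocyte"))) {
    stop("kind must be 'neuron' or 'astrocyte'")
  }
  class(df) <- c("cell_layout", "data.frame")
  df
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream seed for entity i under a base seed.
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1103L + 7919 * as.numeric(i)) %% 2147483647)
}
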