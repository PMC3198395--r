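# End-to-end pipeline driver: simulate -> detect -> average -> map ->
# classify -> report, with strict config validation, a structured run
# log, and a hashed artifact manifest so a seeded run is reproducible
# byte for byte.

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "glia_run",
    simulate = list(
      network = list(burst_rate = 0.11, rate_jitter_cv = 0.2,
                     burst_half_width = 0.79, burst_amplitude = 1,
                     duration = 300, sample_rate = 200, noise_sd = 0.02),
      astro = list(R_m = 29, V_hold = -70, K_out_base = 8, K_in = 140,
                   delta_K = 0.05, temperature = 303, glt_amp = -1,
                   barium_factor = 1, glt_factor = 1, noise_sd = 10,
                   kernel_tau = 1),
      imaging = list(frame_rate = 5, size = c(48, 48), n_neurons = 3,
                     n_astro = 5, n_astro_spont = 2, transient_amp = 0.5,
                     spont_rate = 3, neuron_decay_tau = 1,
                     astro_decay_tau = 3)
    ),
    detect = list(threshold_k = 4, refractory = 2),
    cta = list(window = c(-5, 15), min_cycles = 6),
    stack_cta = list(n_pre = 35, n_post = 30, min_cycles = 5,
                     max_cycles = 20),
    classify = list(k = 3, min_dur = 0.4),
    ccmap = list(max_lag_frames = 0)
  )
}

# merge user config over defaults; unknown keys anywhere are rejected
merge_config <- function(user, defaults = default_config(),
                         path = "config") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s) under %s: %s", path,
                 paste(unknown, collapse = ", ")))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(user[[k]], defaults[[k]],
                                    paste(path, k, sep = "."))
    } else defaults[[k]] <- user[[k]]
  }
  defaults
}

# deterministic layout for the simulated field of view
standard_layout <- function(im) {
  n <- im$n_neurons + im$n_astro
  # cells on a grid with margins
  per_row <- ceiling(sqrt(n))
  step_r <- (im$size[1L] - 12) / per_row
  step_c <- (im$size[2L] - 12) / per_row
  idx <- seq_len(n) - 1L
  centers_r <- 7 + (idx %/% per_row) * step_r
  centers_c <- 7 + (idx %% per_row) * step_c
  kind <- c(rep("neuron", im$n_neurons), rep("astrocyte", im$n_astro))
  rhythmic <- kind == "neuron"
  spont <- numeric(n)
  if (im$n_astro_spont > 0) {
    sp_idx <- which(kind == "astrocyte")[seq_len(im$n_astro_spont)]
    spont[sp_idx] <- im$spont_rate
  }
  cell_layout(id = sprintf("%s%02d", ifelse(kind == "neuron", "N", "A"),
                           seq_len(n)),
              kind = kind, center_row = centers_r, center_col = centers_c,
              radius = 4, rhythmic = rhythmic, spont_rate = spont,
              transient_amp = ifelse(rhythmic | spont > 0,
                                     im$transient_amp, 0),
              decay_tau = ifelse(kind == "neuron", im$neuron_decay_tau,
                                 im$astro_decay_tau))
}

#' Run the full simulate-and-analyze pipeline
#'
#' Executes, in order: synthetic network + astrocyte-current + imaging
#' simulation, burst detection on the integrated field potential,
#' cycle-triggered averaging of the whole-cell current with I_resp,A
#' quantification, stack cycle-triggered averaging, a pixel-wise
#' cross-correlation map against the first rhythmic neuron, per-cell
#' classification, and a cohort summary. Every stage's outputs are
#' written before the next starts; a manifest lists each artifact with
#' its MD5 hash. All randomness flows from `config$seed`.
#'
#' @param config nested list overriding the defaults (see
#'   `gliarhythm:::default_config()`); unknown keys are rejected before
#'   any stage runs.
#' @return list: `paths` of written artifacts, `manifest`
#'   (file -> md5), `summary` (classification + I_resp,A), `config`
#'   (fully resolved).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- merge_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(stage, fmt, ...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  paths <- character(0)
  emit <- function(p) { paths <<- c(paths, p); p }

  # --- stage: simulate -------------------------------------------------
  np <- do.call(network_params, c(cfg$simulate$network,
                                  list(seed = cfg$seed)))
  net <- simulate_burst_train(np)
  say("simulate", "%d bursts over %g s", length(net$bursts$peak_times),
      np$duration)
  ap <- do.call(astro_params, cfg$simulate$astro)
  cur <- simulate_astrocyte_current(net$bursts, ap,
                                    sample_rate = np$sample_rate,
                                    seed = substream_seed(cfg$seed, 2L))
  im <- cfg$simulate$imaging
  layout <- standard_layout(im)
  stack <- simulate_imaging_stack(net$bursts, layout,
                                  frame_rate = im$frame_rate,
                                  size = im$size,
                                  seed = substream_seed(cfg$seed, 3L))
  emit(write_trace(net$trace, file.path(cfg$out_dir, "field_potential.csv")))
  emit(write_trace(cur$trace, file.path(cfg$out_dir, "astro_current.csv")))
  emit(write_stack(list(ch1 = stack$ch1, ch2 = stack$ch2),
                   stack$frame_times, stack$trigger_times, cfg$out_dir,
                   prefix = "stack", pixel_size_um = stack$pixel_size_um))
  emit(write_manifest(list(burst_times_s = net$bursts$peak_times,
                           iresp_true_pA = cur$ground_truth$amplitude,
                           cells = stack$ground_truth$layout),
                      file.path(cfg$out_dir, "ground_truth.json")))

  # --- stage: detect ---------------------------------------------------
  bursts <- detect_bursts(net$trace, threshold_k = cfg$detect$threshold_k,
                          refractory = cfg$detect$refractory)
  bm <- burst_metrics(bursts)
  say("detect", "%d bursts, %.3f Hz", bm$n_bursts, bm$frequency)

  # --- stage: cta-current ----------------------------------------------
  avg <- cta_current(cur$trace, bursts, window = cfg$cta$window,
                     min_cycles = cfg$cta$min_cycles)
  iresp <- measure_iresp(avg)
  say("cta-current", "I_resp,A = %.2f pA from %d cycles", iresp,
      avg$n_cycles)
  utils::write.csv(data.frame(rel_time_s = avg$rel_time,
                              mean_pA = avg$mean_values),
                   emit(file.path(cfg$out_dir, "cycle_average.csv")),
                   row.names = FALSE)

  # --- stage: cta-stack + ccmap ---------------------------------------
  sa <- cta_stack(stack$ch2, stack$frame_times, bursts$peak_times,
                  n_pre = cfg$stack_cta$n_pre,
                  n_post = cfg$stack_cta$n_post,
                  min_cycles = cfg$stack_cta$min_cycles,
                  max_cycles = cfg$stack_cta$max_cycles,
                  rois = stack$rois)
  ref_id <- layout$id[layout$kind == "neuron" & layout$rhythmic][1L]
  ref_f <- extract_roi_traces(stack$ch2, stack$rois[ref_id])[, 1L]
  ref_dff <- compute_dff(ref_f)
  cc <- compute_cc_map(stack$ch2, ref_dff,
                       max_lag_frames = cfg$ccmap$max_lag_frames)
  cc_out <- unclass(cc); cc_out[!is.finite(cc_out)] <- 0
  tiff::writeTIFF((cc_out + 1) / 2,
                  emit(file.path(cfg$out_dir, "cc_map.tif")),
                  bits.per.sample = 32L)
  say("ccmap", "reference ROI %s; CC range [%.2f, %.2f]", ref_id,
      min(cc, na.rm = TRUE), max(cc, na.rm = TRUE))

  # --- stage: classify -------------------------------------------------
  cls <- classify_cells(stack$ch2, stack$frame_times, bursts$peak_times,
                        stack$rois, n_pre = cfg$stack_cta$n_pre,
                        n_post = cfg$stack_cta$n_post,
                        k = cfg$classify$k, min_dur = cfg$classify$min_dur,
                        min_cycles = cfg$stack_cta$min_cycles,
                        max_cycles = cfg$stack_cta$max_cycles)
  cls$kind <- layout$kind[match(cls$roi, layout$id)]
  utils::write.csv(cls, emit(file.path(cfg$out_dir, "classification.csv")),
                   row.names = FALSE)
  say("classify", "%d/%d astrocytes rhythmic, %d/%d neurons rhythmic",
      sum(cls$rhythmic[cls$kind == "astrocyte"]),
      sum(cls$kind == "astrocyte"),
      sum(cls$rhythmic[cls$kind == "neuron"]),
      sum(cls$kind == "neuron"))

  # --- stage: report ---------------------------------------------------
  astro <- cls[cls$kind == "astrocyte", ]
  summary <- list(
    burst_frequency_hz = bm$frequency,
    burst_half_width_s = bm$mean_half_width,
    iresp_pA = iresp,
    iresp_true_pA = cur$ground_truth$amplitude,
    astro_rhythmic_pct = proportion_pct(sum(astro$rhythmic), nrow(astro)),
    astro_spont_pct = proportion_pct(sum(astro$spont_active), nrow(astro)),
    n_cycles = avg$n_cycles)
  emit(write_manifest(summary, file.path(cfg$out_dir, "report.json")))
  emit(write_manifest(cfg, file.path(cfg$out_dir, "config_resolved.json")))
  writeLines(log_lines, emit(file.path(cfg$out_dir, "run_log.txt")))

  manifest <- as.list(tools::md5sum(sort(unname(paths))))
  write_manifest(manifest, file.path(cfg$out_dir, "manifest.json"))
  list(paths = paths, manifest = manifest, summary = summary,
       classification = cls, config = cfg)
}
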