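#!/usr/bin/env Rscript
# Generate the synthetic study dataset at the control conditions:
# a 600 s rhythmic-slice recording (integrated field potential at
# 0.11 Hz, interval CV 0.2, burst half-width 0.79 s), the whole-cell
# current of a passive astrocyte carrying a -5.9 pA burst-locked inward
# component buried in 10 pA noise, and a two-channel calcium-imaging
# stack with rhythmic neurons and arrhythmic astrocytes.
#
# Everything downstream (02-04) reads the files written here.

suppressPackageStartupMessages(library(gliarhythm))

seed <- 20260924L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

np <- network_params(burst_rate = 0.11, rate_jitter_cv = 0.2,
                     burst_half_width = 0.79, duration = 600,
                     sample_rate = 200, noise_sd = 0.02, seed = seed)
net <- simulate_burst_train(np)
cat(sprintf("field potential: %d bursts in %g s (%.3f Hz)\n",
            length(net$bursts$peak_times), np$duration,
            length(net$bursts$peak_times) / np$duration))

a <- astro_params(R_m = 29, V_hold = -70, noise_sd = 10,
                  delta_K = delta_k_for_amplitude(5.9, astro_params()))
cur <- simulate_astrocyte_current(net$bursts, a, sample_rate = 200,
                                  seed = seed + 1L)
cat(sprintf("astrocyte current: true burst-locked amplitude %.2f pA in %g pA noise\n",
            cur$ground_truth$amplitude, a$noise_sd))

lay <- cell_layout(
  id = c("N1", "N2", "N3", "A1", "A2", "A3", "A4", "A5"),
  kind = c(rep("neuron", 3), rep("astrocyte", 5)),
  center_row = c(8, 8, 24, 24, 40, 40, 56, 56),
  center_col = c(8, 40, 8, 40, 8, 40, 24, 56),
  radius = 4, rhythmic = c(rep(TRUE, 3), rep(FALSE, 5)),
  spont_rate = c(0, 0, 0, 3, 3, 0, 0, 0), transient_amp = 0.5,
  decay_tau = c(1, 1, 1, rep(3, 5)))
stack <- simulate_imaging_stack(net$bursts, lay, frame_rate = 5,
                                size = c(64, 64), duration = 300,
                                seed = seed + 2L)
cat(sprintf("imaging: %d frames, %d cells (%d rhythmic neurons, %d astrocytes)\n",
            length(stack$frame_times), nrow(lay), sum(lay$rhythmic),
            sum(lay$kind == "astrocyte")))

write_trace(net$trace, file.path(out, "field_potential.csv"))
write_trace(cur$trace, file.path(out, "astro_current.csv"))
write_stack(list(ch1 = stack$ch1, ch2 = stack$ch2), stack$frame_times,
            stack$trigger_times, out, prefix = "stack")
write_manifest(list(seed = seed,
                    burst_times_s = net$bursts$peak_times,
                    iresp_true_pA = cur$ground_truth$amplitude,
                    cells = lay,
                    rois = lapply(stack$rois, as.data.frame)),
               file.path(out, "ground_truth.json"))
cat("wrote", out, "\n")
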