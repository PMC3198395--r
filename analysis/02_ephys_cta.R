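#!/usr/bin/env Rscript
# Electrophysiology analysis of the simulated slice: burst detection and
# metrics on the integrated field potential, cycle-triggered averaging
# of the whole-cell astrocytic current, I_resp,A quantification, and the
# pharmacology-style comparisons (Kir block scaling the potassium
# component, transporter block removing the GLT component), plus the
# passive-membrane characterization (IV linearity, input resistance).
#
# Requires analysis/01_simulate.R to have run.

suppressPackageStartupMessages(library(gliarhythm))

dat <- "results/data"
dir.create("results", showWarnings = FALSE)
fp <- read_trace(file.path(dat, "field_potential.csv"))
cur <- read_trace(file.path(dat, "astro_current.csv"), require_v_hold = TRUE)
gt <- jsonlite::read_json(file.path(dat, "ground_truth.json"),
                          simplifyVector = TRUE)

bursts <- detect_bursts(fp)
bm <- burst_metrics(bursts, duration = length(fp$values) / fp$sample_rate)
cat(sprintf("bursts: n=%d, rate %.3f Hz, half-width %.2f s, amplitude %.2f a.u.\n",
            bm$n_bursts, bm$frequency, bm$mean_half_width,
            bm$mean_amplitude))

avg <- cta_current(cur, bursts)
iresp <- measure_iresp(avg)
cat(sprintf("I_resp,A: %.2f pA from %d cycles (ground truth %.2f pA)\n",
            iresp, avg$n_cycles, gt$iresp_true_pA))

# Kir-block experiment: the potassium component alone at -6.7 pA, then
# scaled to 45 % of its control size; amplitudes re-measured by CTA.
seed <- 20260924L
np <- network_params(burst_rate = 0.11, rate_jitter_cv = 0.2,
                     duration = 400, sample_rate = 200, noise_sd = 0.02,
                     seed = seed + 10L)
net <- simulate_burst_train(np)
trg <- detect_bursts(net$trace)
mk_iresp <- function(a, s) {
  sim <- simulate_astrocyte_current(net$bursts, a, sample_rate = 200,
                                    seed = s)
  measure_iresp(cta_current(sim$trace, trg))
}
a_ctrl <- astro_params(R_m = 29, V_hold = -70, noise_sd = 10,
                       delta_K = delta_k_for_amplitude(6.7, astro_params()))
a_ba <- a_ctrl; a_ba$barium_factor <- 0.45; class(a_ba) <- "astro_params"
i_ctrl <- mk_iresp(a_ctrl, seed + 11L)
i_ba <- mk_iresp(a_ba, seed + 11L)
red_ba <- percent_reduction(i_ctrl, i_ba)
cat(sprintf("Kir block: %.2f -> %.2f pA, reduction %.1f %% (> 50 %%: %s)\n",
            i_ctrl, i_ba, red_ba, red_ba > 50))

# Transporter-block experiment: -3.8 pA total as -1.4 pA potassium plus
# -2.4 pA transporter current; blocking the transporter leaves the
# potassium part.
a_pre <- astro_params(R_m = 29, V_hold = -70, noise_sd = 10,
                      delta_K = delta_k_for_amplitude(1.4, astro_params()),
                      glt_amp = -2.4)
a_dhk <- a_pre; a_dhk$glt_factor <- 0; class(a_dhk) <- "astro_params"
i_pre <- mk_iresp(a_pre, seed + 12L)
i_dhk <- mk_iresp(a_dhk, seed + 12L)
cat(sprintf("GLT block: %.2f -> %.2f pA, reduction %.1f %%\n",
            i_pre, i_dhk, percent_reduction(i_pre, i_dhk)))

# IV relation of the burst-locked current across holding potentials:
# amplitudes normalized to the largest current over the range.
vh <- seq(-90, 20, by = 10)
iv_amp <- vapply(vh, function(v) {
  av <- astro_params(R_m = 29, V_hold = v, noise_sd = 10,
                     delta_K = delta_k_for_amplitude(6.7, astro_params()))
  mk_iresp(av, seed + 13L)
}, numeric(1))
iv <- normalize_iv(vh, iv_amp)

# passive characterization and input resistance
sp <- simulate_step_protocol(astro_params(R_m = 29, noise_sd = 5),
                             steps = seq(-80, 100, by = 10),
                             seed = seed + 14L)
res <- analyze_step_protocol(sp)
pv <- classify_passive(res$step_voltages, res$steady_state_deltas)
cat(sprintf("step protocol: R_in %.1f MOhm, IV r2 %.4f, passive: %s\n",
            res$R_in, res$linearity_r2, pv$passive))

utils::write.csv(data.frame(rel_time_s = avg$rel_time,
                            mean_pA = avg$mean_values),
                 "results/cycle_average.csv", row.names = FALSE)
utils::write.csv(data.frame(v_hold_mv = iv$holding_potentials,
                            iresp_pA = iv$amplitudes,
                            i_over_imax = iv$normalized),
                 "results/iv_normalized.csv", row.names = FALSE)
write_manifest(list(
  burst_rate_hz = bm$frequency, burst_half_width_s = bm$mean_half_width,
  iresp_pA = iresp, iresp_true_pA = gt$iresp_true_pA,
  n_cycles = avg$n_cycles,
  barium = list(control_pA = i_ctrl, barium_pA = i_ba,
                reduction_pct = red_ba),
  glt = list(pre_pA = i_pre, dhk_pA = i_dhk,
             reduction_pct = percent_reduction(i_pre, i_dhk)),
  r_in_mohm = res$R_in, iv_r2 = res$linearity_r2),
  "results/ephys_summary.json")
cat("wrote results/ephys_summary.json\n")
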