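#!/usr/bin/env Rscript
# Cohort report: proportions and mean +/- SEM from the simulated
# classification, a paired comparison of the pharmacology-style CTA
# amplitudes, and the worked examples on published cohort counts that
# anchor the percentage convention (half-up, one decimal).
#
# Requires analysis/02 and 03 to have run.

suppressPackageStartupMessages(library(gliarhythm))

cls <- utils::read.csv("results/classification.csv")
eph <- jsonlite::read_json("results/ephys_summary.json",
                           simplifyVector = TRUE)

astro <- cls[cls$kind == "astrocyte", ]
summ <- list(
  astro_rhythmic = cohort_summary("rhythmic astrocytes",
                                  sum(astro$rhythmic), nrow(astro)),
  astro_spont = cohort_summary("spontaneously active astrocytes",
                               sum(astro$spont_active), nrow(astro)),
  neurons_rhythmic = cohort_summary("rhythmic neurons",
                                    sum(cls$rhythmic[cls$kind == "neuron"]),
                                    sum(cls$kind == "neuron")))
for (s in summ) print(s)

cat(sprintf("Kir-block reduction: %.1f %% | transporter-block reduction: %.1f %%\n",
            eph$barium$reduction_pct, eph$glt$reduction_pct))

# paired comparison across a small simulated cohort of cells:
# control vs Kir-block amplitudes, cell-wise
seed <- 20260924L
pairs <- t(vapply(1:8, function(i) {
  np <- network_params(burst_rate = 0.11, rate_jitter_cv = 0.2,
                       duration = 300, sample_rate = 200,
                       noise_sd = 0.02, seed = seed + 100L + i)
  net <- simulate_burst_train(np)
  trg <- detect_bursts(net$trace)
  a1 <- astro_params(R_m = 29, V_hold = -70, noise_sd = 10,
                     delta_K = delta_k_for_amplitude(6.7, astro_params()))
  a2 <- a1; a2$barium_factor <- 0.45; class(a2) <- "astro_params"
  c(ctrl = measure_iresp(cta_current(
      simulate_astrocyte_current(net$bursts, a1, 200,
                                 seed = seed + 200L + i)$trace, trg)),
    ba = measure_iresp(cta_current(
      simulate_astrocyte_current(net$bursts, a2, 200,
                                 seed = seed + 200L + i)$trace, trg)))
}, numeric(2)))
ms_ctrl <- mean_sem(pairs[, "ctrl"]); ms_ba <- mean_sem(pairs[, "ba"])
pc <- paired_compare(pairs[, "ctrl"], pairs[, "ba"])
cat(sprintf("cohort (n=%d): control %.2f +/- %.2f pA vs block %.2f +/- %.2f pA, %s p = %.4g\n",
            nrow(pairs), ms_ctrl$mean, ms_ctrl$sem, ms_ba$mean,
            ms_ba$sem, pc$method, pc$p_value))

# worked examples on published cohort counts (percentage convention)
printed <- data.frame(
  n_positive = c(59, 38, 61, 304, 22),
  n_total = c(569, 300, 307, 307, 25))
printed$pct <- mapply(proportion_pct, printed$n_positive, printed$n_total)
print(printed)

write_manifest(list(
  cohorts = lapply(summ, unclass),
  paired_test = pc,
  control_mean_sem_pA = ms_ctrl,
  block_mean_sem_pA = ms_ba,
  printed_count_examples = printed),
  "results/report.json")
cat("wrote results/report.json\n")
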