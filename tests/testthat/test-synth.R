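# Synthetic generator: burst trains, passive-membrane currents, step
# protocols, imaging stacks, and their ground-truth manifests.

test_that("regular burst train has the exact count and spacing", {
  np <- network_params(burst_rate = 0.11, rate_jitter_cv = 0,
                       duration = 600, sample_rate = 200,
                       noise_sd = 0.02, seed = 1)
  net <- simulate_burst_train(np)
  expect_length(net$bursts$peak_times, 66L)   # 600 s x 0.11 Hz
  expect_equal(diff(net$bursts$peak_times),
               rep(1 / 0.11, 65), tolerance = 1e-12)
  expect_length(net$trace$values, 600 * 200)
})

test_that("zero burst rate yields an empty train and a pure-noise trace", {
  np <- network_params(burst_rate = 0, duration = 100, sample_rate = 200,
                       noise_sd = 0.05, seed = 2)
  net <- simulate_burst_train(np)
  expect_length(net$bursts$peak_times, 0L)
  expect_equal(sd(net$trace$values), 0.05, tolerance = 0.05)
  expect_equal(mean(net$trace$values), 0, tolerance = 0.005)
})

test_that("jittered trains reproduce the configured mean rate", {
  rates <- vapply(1:12, function(s) {
    np <- network_params(burst_rate = 0.11, rate_jitter_cv = 0.2,
                         duration = 2000, sample_rate = 50,
                         noise_sd = 0, seed = s)
    length(simulate_burst_train(np)$bursts$peak_times) / 2000
  }, numeric(1))
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.11), 3 * se + 1e-12)
})

test_that("generator parameter validation rejects non-physical values", {
  expect_error(network_params(burst_rate = -1), "burst_rate")
  expect_error(network_params(burst_half_width = 0), "burst_half_width")
  expect_error(astro_params(K_out_base = 0), "concentration")
  expect_error(astro_params(barium_factor = 1.2), "barium_factor")
})

test_that("potassium-shift amplitude follows the Nernst relation", {
  a <- astro_params(R_m = 29, V_hold = -70, K_out_base = 8, K_in = 140,
                    delta_K = 0.05, temperature = 303, glt_amp = 0,
                    noise_sd = 0)
  bt <- burst_train(c(20, 40, 60), duration = 80)
  sim <- simulate_astrocyte_current(bt, a, sample_rate = 200)
  # closed form: dI = -1000 * dE_K / R_m, dE_K = (RT/F) ln(K1/K0)
  rtf_mv <- 1000 * 8.314462618 * 303 / 96485.33212
  expected <- -1000 * rtf_mv * log(8.05 / 8) / 29
  expect_equal(sim$ground_truth$amplitude, expected, tolerance = 1e-12)
  expect_equal(expected, -5.6, tolerance = 0.01 / 5.6 + 0.002)
  # rendered noise-free burst-locked extremum matches the analytic peak
  base <- sim$ground_truth$baseline_pA
  expect_equal(min(sim$trace$values) - base, expected, tolerance = 1e-3)
})

test_that("ground-truth amplitude equals the analytic kernel peak", {
  a <- astro_params(delta_K = 0.1, glt_amp = -2, glt_factor = 0.7,
                    barium_factor = 0.8, noise_sd = 0)
  bt <- burst_train(50, duration = 100)
  sim <- simulate_astrocyte_current(bt, a, sample_rate = 500)
  rtf_mv <- 1000 * 8.314462618 * a$temperature / 96485.33212
  amp_k <- -0.8 * 1000 * rtf_mv * log(8.1 / 8) / a$R_m
  expect_equal(sim$ground_truth$amplitude, amp_k + 0.7 * (-2),
               tolerance = 1e-9)
})

test_that("current superposes its potassium and transporter components", {
  bt <- burst_train(c(10, 25, 40), duration = 60)
  base <- list(R_m = 29, V_hold = -70, delta_K = 0.06, glt_amp = -3,
               noise_sd = 0)
  full <- simulate_astrocyte_current(
    bt, do.call(astro_params, base), sample_rate = 200)
  k_only <- simulate_astrocyte_current(
    bt, do.call(astro_params, c(base["R_m"], base["V_hold"],
                                base["delta_K"],
                                list(glt_amp = -3, glt_factor = 0,
                                     noise_sd = 0))), sample_rate = 200)
  g_only <- simulate_astrocyte_current(
    bt, do.call(astro_params, c(base["R_m"], base["V_hold"],
                                list(delta_K = 0.06, barium_factor = 0,
                                     glt_amp = -3, noise_sd = 0))),
    sample_rate = 200)
  expect_equal(full$trace$values,
               k_only$trace$values + g_only$trace$values,
               tolerance = 1e-12)
})

test_that("barium factor scales the potassium component linearly", {
  bt <- burst_train(c(10, 25, 40), duration = 60)
  mk <- function(bf) simulate_astrocyte_current(
    bt, astro_params(delta_K = 0.06, glt_amp = 0, barium_factor = bf,
                     noise_sd = 0), sample_rate = 200)
  a1 <- mk(1); a45 <- mk(0.45)
  expect_equal(a45$ground_truth$amplitude,
               0.45 * a1$ground_truth$amplitude, tolerance = 1e-12)
  expect_equal(a45$trace$values, 0.45 * a1$trace$values,
               tolerance = 1e-12)
})

test_that("flat-baseline current with no burst-locked component averages to zero", {
  np <- network_params(burst_rate = 0.11, rate_jitter_cv = 0,
                       duration = 300, sample_rate = 100, seed = 3)
  net <- simulate_burst_train(np)
  a <- astro_params(delta_K = 0, glt_amp = 0, noise_sd = 5)
  sim <- simulate_astrocyte_current(net$bursts, a, sample_rate = 100,
                                    seed = 11)
  expect_equal(sim$ground_truth$amplitude, 0)
  avg <- cta_current(sim$trace, net$bursts)
  expect_lt(abs(measure_iresp(avg)), 1)   # noise floor only
})

test_that("step protocol obeys Ohm's law and is linear", {
  a0 <- astro_params(R_m = 29, noise_sd = 0)
  sp <- simulate_step_protocol(a0, steps = c(-10), seed = 1)
  r <- measure_input_resistance(sp$traces[[1]], -10, sp$step_window)
  expect_equal(r$delta_I, -10000 / 29, tolerance = 1e-9)   # -344.83 pA
  sp0 <- simulate_step_protocol(a0, steps = c(0, 10), seed = 1)
  expect_equal(mean(sp0$traces[[1]]$values), 0, tolerance = 1e-12)
  spl <- simulate_step_protocol(a0, steps = seq(-80, 100, by = 10),
                                seed = 1)
  res <- analyze_step_protocol(spl)
  expect_equal(res$linearity_r2, 1, tolerance = 1e-9)
  expect_equal(res$R_in, 29, tolerance = 1e-9)
  expect_error(simulate_step_protocol(a0, steps = numeric(0)), "nonempty")
})

test_that("identical seeds reproduce every synthetic output exactly", {
  np <- network_params(duration = 60, seed = 7)
  expect_identical(simulate_burst_train(np), simulate_burst_train(np))
  bt <- simulate_burst_train(np)$bursts
  a <- astro_params()
  expect_identical(
    simulate_astrocyte_current(bt, a, sample_rate = 100, seed = 3),
    simulate_astrocyte_current(bt, a, sample_rate = 100, seed = 3))
  lay <- two_cell_layout(spont_rate_astro = 3)
  s1 <- simulate_imaging_stack(bt, lay, frame_rate = 5, size = c(64, 64),
                               seed = 5)
  s2 <- simulate_imaging_stack(bt, lay, frame_rate = 5, size = c(64, 64),
                               seed = 5)
  expect_identical(s1, s2)
})

test_that("imaging stack separates channels and honours quiet layouts", {
  bt <- burst_train(c(10, 20, 30), duration = 40)
  lay <- cell_layout(id = c("N1", "A1"), kind = c("neuron", "astrocyte"),
                     center_row = c(12, 40), center_col = c(12, 40),
                     radius = 4, rhythmic = FALSE, spont_rate = 0,
                     transient_amp = 0, decay_tau = 1)
  st <- simulate_imaging_stack(bt, lay, frame_rate = 5, size = c(64, 64),
                               noise_floor = 0.5, noise_gain = 0,
                               seed = 9)
  # channel 1 marks astrocytes only
  expect_gt(mean(st$ch1[, 40, 40]), 50)
  expect_lt(mean(st$ch1[, 12, 12]), 5)
  # no transients anywhere: ROI means are constant up to averaged noise
  tr <- extract_roi_traces(st$ch2, st$rois)
  expect_lt(max(apply(tr, 2, sd)), 3 * 0.5 / sqrt(nrow(st$rois[[1]])))
  expect_lt(max(abs(apply(tr, 2, mean) - 100)), 1)
  expect_error(simulate_imaging_stack(bt, lay, frame_rate = 0),
               "frame_rate")
})
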