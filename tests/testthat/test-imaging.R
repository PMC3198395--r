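# Imaging analysis: rolling-ball background, ROI traces, dF/F0, stack
# averaging, cross-correlation maps, rhythmicity and event detection.

test_that("rolling-ball subtraction matches the brute-force opening oracle", {
  set.seed(21)
  img <- matrix(runif(32 * 32, 0, 1), 32, 32)
  img[10:14, 20:24] <- img[10:14, 20:24] + 3
  for (radius in c(3, 6.5)) {
    bg_oracle <- oracle_ball_opening(img, radius)
    expect_equal(rolling_ball_subtract(img, radius),
                 pmax(img - bg_oracle, 0), tolerance = 1e-12)
  }
})

test_that("rolling ball removes flat background and keeps small features", {
  expect_equal(rolling_ball_subtract(matrix(7, 20, 20), 5),
               matrix(0, 20, 20))
  img <- matrix(10, 48, 48)
  rows <- matrix(seq_len(48), 48, 48)
  cols <- t(rows)
  disk <- (rows - 24)^2 + (cols - 24)^2 <= 3^2
  img[disk] <- 60
  out <- rolling_ball_subtract(img, 30)
  expect_equal(max(out), 50, tolerance = 0.05 * 50)
  expect_lt(max(out[!disk]), 1)
  expect_error(rolling_ball_subtract(img, 0.5), "radius")
})

test_that("huge ball radius approaches global-minimum subtraction", {
  set.seed(22)
  img <- matrix(runif(16 * 16, 10, 12), 16, 16)
  resid <- vapply(c(23, 200, 2000), function(r)
    max(abs(rolling_ball_subtract(img, r) - (img - min(img)))),
    numeric(1))
  expect_true(all(diff(resid) < 0))   # monotone approach to the limit
  expect_lt(resid[3], 0.1)            # sag d^2/(8r) at r = 2000
})

test_that("ROI traces equal per-region means computed by brute force", {
  set.seed(23)
  stack <- array(rnorm(30 * 12 * 12, 50, 5), dim = c(30, 12, 12))
  rois <- list(a = cbind(row = c(2, 3, 4), col = c(2, 2, 3)),
               b = cbind(row = 10, col = 11))
  tr <- extract_roi_traces(stack, rois)
  brute_a <- sapply(1:30, function(t)
    mean(c(stack[t, 2, 2], stack[t, 3, 2], stack[t, 4, 3])))
  expect_equal(unname(tr[, "a"]), brute_a, tolerance = 1e-12)
  expect_equal(unname(tr[, "b"]), stack[, 10, 11], tolerance = 1e-12)
  # constant stack gives a constant trace; empty ROI is skipped
  cst <- array(4, dim = c(5, 4, 4))
  expect_true(all(extract_roi_traces(cst, list(p = cbind(row = 2,
                                                         col = 3))) == 4))
  expect_warning(
    tr2 <- extract_roi_traces(stack, c(rois, list(e = cbind(row = integer(0),
                                                            col = integer(0))))),
    "empty ROI")
  expect_identical(colnames(tr2), c("a", "b"))
})

test_that("dF/F0 is correct, scale-invariant and guards its baseline", {
  f <- rep(10, 100)
  expect_true(all(compute_dff(f)$dff == 0))
  f2 <- c(rep(10, 50), rep(20, 50))
  d <- compute_dff(f2, list(window = c(0, 9), times = 0:99))
  expect_equal(unique(d$dff), c(0, 1))
  expect_equal(compute_dff(7 * f2)$dff, compute_dff(f2)$dff,
               tolerance = 1e-12)
  expect_error(compute_dff(c(-5, -5, 1)), "baseline")
})

test_that("reference-peak detection finds transients and documents its floor", {
  bt <- burst_train(seq(15, 110, by = 9), duration = 120)
  lay <- two_cell_layout()
  st <- simulate_imaging_stack(bt, lay, frame_rate = 5, size = c(64, 64),
                               seed = 31)
  dff <- compute_dff(extract_roi_traces(st$ch2, st$rois["N1"])[, 1])
  pk <- detect_reference_peaks(dff, st$frame_times)
  expect_length(pk, length(bt$peak_times))
  expect_lt(max(abs(pk - bt$peak_times)), 1 / 5 + 1e-9)  # within 1 frame
  expect_length(detect_reference_peaks(rep(0, 500), (0:499) / 5), 0L)
  # sensitivity contract: a transient at 2x the noise SD stays below a
  # k = 4 threshold
  set.seed(32)
  weak <- rnorm(500, 0, 0.05)
  weak[250:252] <- weak[250:252] + 0.1
  expect_length(detect_reference_peaks(weak, (0:499) / 5), 0L)
})

test_that("stack averaging reduces noise as 1/sqrt(N) and guards cycles", {
  sds <- vapply(c(5, 10, 20), function(N) {
    set.seed(40 + N)
    n_fr <- 40 * (N + 2)
    ft <- (seq_len(n_fr) - 1) / 5
    stk <- array(rnorm(n_fr * 4 * 4), dim = c(n_fr, 4, 4))
    trg <- ft[seq(41, by = 40, length.out = N)]
    sa <- cta_stack(stk, ft, trg, n_pre = 10, n_post = 10,
                    min_cycles = 5, max_cycles = N)
    sd(as.vector(sa$frames))
  }, numeric(1))
  expect_equal(sds, 1 / sqrt(c(5, 10, 20)), tolerance = 0.2)
  # constant stack stays constant; too few triggers error
  cst <- array(2, dim = c(100, 3, 3))
  ft <- (0:99) / 5
  sa <- cta_stack(cst, ft, c(5, 8, 11, 14, 17), n_pre = 5, n_post = 5)
  expect_true(all(sa$frames == 2))
  expect_error(cta_stack(cst, ft, c(5, 8, 11, 14), n_pre = 5, n_post = 5),
               "insufficient cycles")
})

test_that("cc map is exact on constructed pixels and bounded on noise", {
  T <- 200
  ref <- sin((1:T) / 5) + (1:T) / 100
  stk <- array(0, dim = c(T, 4, 4))
  stk[, 1, 1] <- 5 * ref + 2      # perfectly correlated
  stk[, 2, 2] <- -ref             # perfectly anticorrelated
  stk[, 3, 3] <- 7                # zero variance
  set.seed(50)
  stk[, 4, 4] <- rnorm(T)
  cc <- compute_cc_map(stk, ref)
  expect_equal(cc[1, 1], 1, tolerance = 1e-12)
  expect_equal(cc[2, 2], -1, tolerance = 1e-12)
  expect_true(is.na(cc[3, 3]))
  expect_error(compute_cc_map(stk, ref[-1]), "length")
  # null bound: independent pixels stay within 3/sqrt(T) nearly always
  hits <- 0; total <- 0
  for (s in 1:6) {
    set.seed(60 + s)
    nstk <- array(rnorm(T * 6 * 6), dim = c(T, 6, 6))
    ncc <- compute_cc_map(nstk, rnorm(T))
    hits <- hits + sum(abs(ncc) <= 3 / sqrt(T))
    total <- total + length(ncc)
  }
  expect_gte(hits / total, 0.99)
})

test_that("cc map of a rhythmic reference lights up coactive cells only", {
  bt <- burst_train(seq(15, 160, by = 9), duration = 170)
  lay <- two_cell_layout()
  st <- simulate_imaging_stack(bt, lay, frame_rate = 5, size = c(64, 64),
                               noise_floor = 0.2, noise_gain = 0,
                               seed = 33)
  dff <- compute_dff(extract_roi_traces(st$ch2, st$rois["N1"])[, 1])
  cc <- compute_cc_map(st$ch2, dff)
  expect_gt(mean(cc[st$rois$N1]), 0.99)   # near-noiseless stack
  expect_lt(abs(mean(cc[st$rois$A1])), 0.2)
})

test_that("rhythmicity call is positive for locked cells and calibrated on noise", {
  # constructed rhythmic average: amplitude 0.5 against noise 0.05
  rel_time <- seq(-4, 6, by = 0.2)
  set.seed(70)
  avg <- 0.5 * exp(-pmax(rel_time, 0)) * (rel_time >= 0) +
    rnorm(length(rel_time), 0, 0.05 / sqrt(10))
  expect_true(classify_rhythmic(avg, rel_time)$rhythmic)
  # false-positive rate on pure noise stays near the nominal level of
  # the max statistic (t-adjusted for the estimated baseline SD)
  n_seeds <- 400
  fp <- 0
  for (s in seq_len(n_seeds)) {
    set.seed(200 + s)
    x <- rnorm(length(rel_time), 0, 0.02)
    fp <- fp + classify_rhythmic(x, rel_time)$rhythmic
  }
  bi <- rel_time < -0.5
  m_resp <- sum(rel_time >= -0.5 & rel_time <= 2)
  p1 <- 2 * stats::pt(-3, df = sum(bi) - 1)
  nominal <- 1 - (1 - p1)^m_resp
  expect_lte(fp / n_seeds,
             nominal + 3 * sqrt(nominal * (1 - nominal) / n_seeds))
})

test_that("arrhythmic spontaneous cells are not called rhythmic", {
  wrong <- 0
  for (s in 1:10) {
    np <- network_params(duration = 200, seed = s)
    net <- simulate_burst_train(np)
    lay <- two_cell_layout(spont_rate_astro = 3)
    st <- simulate_imaging_stack(net$bursts, lay, frame_rate = 5,
                                 size = c(64, 64), seed = 100 + s)
    tr <- extract_roi_traces(st$ch2, st$rois)
    pk <- detect_reference_peaks(compute_dff(tr[, "N1"]), st$frame_times)
    cls <- classify_cells(st$ch2, st$frame_times, pk, st$rois)
    wrong <- wrong + cls$rhythmic[cls$roi == "A1"] +
      !cls$rhythmic[cls$roi == "N1"]
  }
  expect_lte(wrong, 1)
})

test_that("spontaneous-event detection honours threshold and duration gates", {
  ft <- (0:499) / 5
  expect_identical(
    detect_spontaneous_events(rep(0.1, 500), ft)$n_events, 0L)
  set.seed(80)
  x <- rnorm(500, 0, 0.02)
  for (t0 in c(100, 250, 400)) x[t0:(t0 + 6)] <- x[t0:(t0 + 6)] + 0.5
  ev <- detect_spontaneous_events(x, ft, min_dur = 0.4)
  expect_identical(ev$n_events, 3L)
  expect_true(ev$spont_active)
  # single-frame blips below the duration gate are ignored
  y <- rnorm(500, 0, 0.02)
  y[250] <- y[250] + 0.5
  expect_identical(detect_spontaneous_events(y, ft, min_dur = 0.6)$n_events,
                   0L)
})

test_that("end-to-end classification recovers ground truth at high SNR", {
  # transient amplitude >= 10x the dF/F0 pixel noise scale
  agree <- TRUE
  for (s in 1:3) {
    np <- network_params(duration = 200, seed = s)
    net <- simulate_burst_train(np)
    lay <- cell_layout(
      id = c("N1", "N2", "N3", "N4", "N5", "A1", "A2", "A3"),
      kind = c(rep("neuron", 5), rep("astrocyte", 3)),
      center_row = c(8, 8, 24, 24, 40, 40, 56, 56),
      center_col = c(8, 40, 8, 40, 8, 40, 24, 56),
      radius = 4, rhythmic = c(rep(TRUE, 5), rep(FALSE, 3)),
      spont_rate = c(rep(0, 5), 3, 0, 0), transient_amp = 0.5,
      decay_tau = c(rep(1, 5), rep(3, 3)))
    st <- simulate_imaging_stack(net$bursts, lay, frame_rate = 5,
                                 size = c(64, 64), seed = 300 + s)
    tr <- extract_roi_traces(st$ch2, st$rois)
    pk <- detect_reference_peaks(compute_dff(tr[, "N1"]), st$frame_times)
    cls <- classify_cells(st$ch2, st$frame_times, pk, st$rois)
    agree <- agree &&
      identical(cls$rhythmic, lay$rhythmic[match(cls$roi, lay$id)])
  }
  expect_true(agree)
})

test_that("classification is invariant to a global intensity gain", {
  np <- network_params(duration = 160, seed = 12)
  net <- simulate_burst_train(np)
  lay <- two_cell_layout(spont_rate_astro = 3)
  st <- simulate_imaging_stack(net$bursts, lay, frame_rate = 5,
                               size = c(64, 64), seed = 112)
  tr <- extract_roi_traces(st$ch2, st$rois)
  pk <- detect_reference_peaks(compute_dff(tr[, "N1"]), st$frame_times)
  c1 <- classify_cells(st$ch2, st$frame_times, pk, st$rois)
  c2 <- classify_cells(st$ch2 * 11.7, st$frame_times, pk, st$rois)
  expect_equal(c1, c2, tolerance = 1e-9)
})
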