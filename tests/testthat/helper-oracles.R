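# Independent brute-force oracles used to cross-check the package's
# implementations on small inputs.

# Grayscale opening with a ball structuring element, computed by an
# explicit double loop over pixels and offsets (erosion then dilation).
oracle_ball_opening <- function(img, radius) {
  H <- nrow(img); W <- ncol(img)
  offs <- expand.grid(dx = -floor(radius):floor(radius),
                      dy = -floor(radius):floor(radius))
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2, ]
  offs$h <- sqrt(radius^2 - offs$dx^2 - offs$dy^2)
  ero <- matrix(Inf, H, W)
  for (x in seq_len(H)) for (y in seq_len(W)) {
    for (k in seq_len(nrow(offs))) {
      xx <- x + offs$dx[k]; yy <- y + offs$dy[k]
      if (xx >= 1 && xx <= H && yy >= 1 && yy <= W)
        ero[x, y] <- min(ero[x, y], img[xx, yy] - offs$h[k])
    }
  }
  dil <- matrix(-Inf, H, W)
  for (x in seq_len(H)) for (y in seq_len(W)) {
    for (k in seq_len(nrow(offs))) {
      xx <- x + offs$dx[k]; yy <- y + offs$dy[k]
      if (xx >= 1 && xx <= H && yy >= 1 && yy <= W)
        dil[x, y] <- max(dil[x, y], ero[xx, yy] + offs$h[k])
    }
  }
  dil
}

# Exact two-sided signed-rank p-value by full enumeration of all 2^n
# sign assignments (midranks for tied magnitudes).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# A trace with unimodal bursts at known times (Gaussian envelopes).
make_burst_trace <- function(times, duration, sr = 200, amp = 1,
                             sigma = 0.34, noise_sd = 0, seed = 1) {
  tt <- (seq_len(duration * sr) - 1) / sr
  v <- numeric(length(tt))
  for (tb in times) v <- v + amp * exp(-(tt - tb)^2 / (2 * sigma^2))
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + rnorm(length(v), 0, noise_sd)
  }
  glia_trace(v, sr, units = "a.u.")
}

# standard two-cell layout (one rhythmic neuron, one quiet astrocyte)
two_cell_layout <- function(spont_rate_astro = 0, amp = 0.5,
                            astro_decay = 3) {
  cell_layout(id = c("N1", "A1"), kind = c("neuron", "astrocyte"),
              center_row = c(12, 40), center_col = c(12, 40), radius = 4,
              rhythmic = c(TRUE, FALSE),
              spont_rate = c(0, spont_rate_astro),
              transient_amp = amp, decay_tau = c(1, astro_decay))
}
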