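# Calcium-imaging analysis: rolling-ball background subtraction, ROI
# trace extraction, dF/F0, stack cycle-triggered averaging, pixel-wise
# cross-correlation maps, rhythmicity and spontaneous-event
# classification.

# Offsets and height profile of a ball structuring element of the given
# radius: h(dx, dy) = sqrt(r^2 - dx^2 - dy^2) on the disk. Offsets
# larger than the image extent never contribute and can be clipped.
ball_element <- function(radius, max_dx = Inf, max_dy = max_dx) {
  rx <- min(floor(radius), max_dx)
  ry <- min(floor(radius), max_dy)
  dx <- rep(-rx:rx, times = 2L * ry + 1L)
  dy <- rep(-ry:ry, each = 2L * rx + 1L)
  keep <- dx^2 + dy^2 <= radius^2
  dx <- dx[keep]; dy <- dy[keep]
  h <- sqrt(radius^2 - dx^2 - dy^2)
  list(dx = dx, dy = dy, h = h)
}

# Grayscale erosion (op = min, pad +Inf) or dilation (op = max, pad -Inf)
# with a non-flat structuring element; offsets outside the image do not
# contribute.
gray_morph <- function(img, se, dilate = FALSE) {
  H <- nrow(img); W <- ncol(img)
  pad <- if (dilate) -Inf else Inf
  out <- matrix(pad, H, W)
  for (k in seq_along(se$h)) {
    dx <- se$dx[k]; dy <- se$dy[k]; h <- se$h[k]
    r0 <- max(1L, 1L - dx); r1 <- min(H, H - dx)   # destination rows
    c0 <- max(1L, 1L - dy); c1 <- min(W, W - dy)
    if (r0 > r1 || c0 > c1) next
    sr <- r0:r1
    sc <- c0:c1
    shifted <- matrix(pad, H, W)
    shifted[sr, sc] <- img[sr + dx, sc + dy]
    out <- if (dilate) pmax(out, shifted + h) else pmin(out, shifted - h)
  }
  out
}

# min-downsample by integer factor f (edge blocks cover fewer pixels)
block_min <- function(img, f) {
  H <- nrow(img); W <- ncol(img)
  Hs <- ceiling(H / f); Ws <- ceiling(W / f)
  out <- matrix(Inf, Hs, Ws)
  for (i in seq_len(Hs)) for (j in seq_len(Ws)) {
    rr <- ((i - 1L) * f + 1L):min(i * f, H)
    cc <- ((j - 1L) * f + 1L):min(j * f, W)
    out[i, j] <- min(img[rr, cc])
  }
  out
}

# bilinear upsampling of a block-downsampled image back to `dims`,
# sampling block centers
upsample_bilinear <- function(small, f, dims) {
  interp_axis <- function(n_out, n_small) {
    u <- (seq_len(n_out) - 0.5) / f + 0.5
    i0 <- pmin(pmax(floor(u), 1), n_small)
    i1 <- pmin(i0 + 1L, n_small)
    w <- pmin(pmax(u - i0, 0), 1)
    list(i0 = i0, i1 = i1, w = w)
  }
  r <- interp_axis(dims[1L], nrow(small))
  cl <- interp_axis(dims[2L], ncol(small))
  top <- small[r$i0, cl$i0, drop = FALSE] * (1 - matrix(cl$w, dims[1L], dims[2L], byrow = TRUE)) +
    small[r$i0, cl$i1, drop = FALSE] * matrix(cl$w, dims[1L], dims[2L], byrow = TRUE)
  bot <- small[r$i1, cl$i0, drop = FALSE] * (1 - matrix(cl$w, dims[1L], dims[2L], byrow = TRUE)) +
    small[r$i1, cl$i1, drop = FALSE] * matrix(cl$w, dims[1L], dims[2L], byrow = TRUE)
  wr <- matrix(r$w, dims[1L], dims[2L])
  top * (1 - wr) + bot * wr
}

#' Rolling-ball background subtraction
#'
#' Estimates the image background as the grayscale opening with a ball
#' structuring element of the given radius (the surface traced by a ball
#' of that radius rolled under the intensity landscape) and subtracts
#' it. Features smaller than the ball are retained; smooth background is
#' removed. The output is non-negative.
#'
#' For large radii the exact opening is O(radius^2) per pixel, so -- as
#' in the classic ImageJ implementation -- the image is min-downsampled
#' by an integer factor (up to 8), the ball is rolled on the shrunken
#' image with a correspondingly reduced radius, and the background is
#' bilinearly upsampled before subtraction. Radii below 16 px always use
#' the exact path.
#'
#' @param frame numeric matrix (one image frame).
#' @param radius ball radius in pixels (>= 1); 30-50 px suits somata of
#'   ~10 px on slowly varying background.
#' @param shrink integer downsampling factor; NULL (default) selects 1
#'   for radius < 16 and min(8, radius/8) otherwise. 1 forces the exact
#'   opening.
#' @return background-subtracted matrix of the same dimensions.
#' @export
rolling_ball_subtract <- function(frame, radius, shrink = NULL) {
  if (!is.matrix(frame)) stop("frame must be a matrix")
  if (radius < 1) stop("radius must be >= 1 pixel")
  if (is.null(shrink))
    shrink <- if (radius < 16) 1L else min(8L, max(2L, floor(radius / 8)))
  if (shrink <= 1L) {
    se <- ball_element(radius, max_dx = nrow(frame) - 1L,
                       max_dy = ncol(frame) - 1L)
    bg <- gray_morph(gray_morph(frame, se, dilate = FALSE), se,
                     dilate = TRUE)
  } else {
    small <- block_min(frame, shrink)
    se <- ball_element(radius / shrink, max_dx = nrow(small) - 1L,
                       max_dy = ncol(small) - 1L)
    bg_s <- gray_morph(gray_morph(small, se, dilate = FALSE), se,
                       dilate = TRUE)
    bg <- upsample_bilinear(bg_s, shrink, dim(frame))
  }
  out <- frame - bg
  out[out < 0] <- 0    # background never exceeds the true envelope
  out
}

#' Apply rolling-ball subtraction to every frame of a stack
#'
#' @param stack array T x H x W.
#' @param radius ball radius, px.
#' @param shrink see [rolling_ball_subtract()].
#' @return array of the same dimensions.
#' @export
rolling_ball_stack <- function(stack, radius, shrink = NULL) {
  out <- stack
  for (t in seq_len(dim(stack)[1L]))
    out[t, , ] <- rolling_ball_subtract(stack[t, , ], radius,
                                        shrink = shrink)
  out
}

#' Mean-intensity traces over regions of interest
#'
#' @param stack array T x H x W.
#' @param rois named list of pixel index matrices (columns row, col;
#'   1-based), e.g. from [simulate_imaging_stack()] or [read_rois()].
#' @return matrix T x n_roi of per-frame mean intensities; empty ROIs
#'   are skipped with a warning and dropped from the result.
#' @export
extract_roi_traces <- function(stack, rois) {
  if (length(rois) == 0L) stop("rois must be nonempty")
  dm <- dim(stack)
  n_fr <- dm[1L]; H <- dm[2L]
  flat <- matrix(stack, nrow = n_fr)   # columns indexed by (row-1) + (col-1)*H... see below
  keep <- vapply(rois, function(px) NROW(px) > 0L, logical(1))
  if (any(!keep))
    warning(sprintf("skipping empty ROI(s): %s",
                    paste(names(rois)[!keep], collapse = ", ")))
  rois <- rois[keep]
  out <- vapply(rois, function(px) {
    lin <- (px[, 2L] - 1L) * H + px[, 1L]
    if (length(lin) == 1L) flat[, lin] else rowMeans(flat[, lin, drop = FALSE])
  }, numeric(n_fr))
  out <- matrix(out, nrow = n_fr,
                dimnames = list(NULL, names(rois)))
  out
}

#' Relative fluorescence change dF/F0
#'
#' F0 is either a low percentile of the whole trace (default: 10th) or
#' the mean over a fixed time window; the result is (F - F0)/F0 and is
#' invariant to any overall intensity gain.
#'
#' @param f numeric fluorescence trace.
#' @param f0_rule list: `list(percentile = p)` (p in percent) or
#'   `list(window = c(t1, t2), times = frame_times)`.
#' @return list of class `dff_trace`: `dff`, `f0`, `f0_rule`.
#' @export
compute_dff <- function(f, f0_rule = list(percentile = 10)) {
  if (!is.null(f0_rule$percentile)) {
    f0 <- as.numeric(stats::quantile(f, f0_rule$percentile / 100,
                                     names = FALSE, type = 7))
  } else if (!is.null(f0_rule$window)) {
    if (is.null(f0_rule$times))
      stop("window-based F0 needs `times` in the rule")
    sel <- f0_rule$times >= f0_rule$window[1L] &
      f0_rule$times <= f0_rule$window[2L]
    if (!any(sel)) stop("F0 window contains no samples")
    f0 <- mean(f[sel])
  } else stop("f0_rule must specify `percentile` or `window`")
  if (f0 <= 0) stop("degenerate baseline: F0 <= 0")
  structure(list(dff = (f - f0) / f0, f0 = f0, f0_rule = f0_rule),
            class = "dff_trace")
}

#' Detect calcium-transient peaks on a reference ROI trace
#'
#' A dF/F0 trace from an inspiratory neuron serves as the optical
#' trigger source; the detector contract is the same as
#' [detect_bursts()] (median + k robust SDs, refractory separation).
#'
#' @param dff numeric dF/F0 trace (or a `dff_trace`).
#' @param frame_times frame timestamps, s.
#' @param threshold_k threshold in robust SDs.
#' @param refractory minimum peak separation, s.
#' @return numeric vector of trigger times, s (possibly empty).
#' @export
detect_reference_peaks <- function(dff, frame_times, threshold_k = 4,
                                   refractory = 2) {
  if (inherits(dff, "dff_trace")) dff <- dff$dff
  sr <- 1 / stats::median(diff(frame_times))
  tr <- glia_trace(dff, sr, t0 = frame_times[1L], units = "dFF0")
  detect_bursts(tr, threshold_k = threshold_k,
                refractory = refractory)$peak_times
}

#' Cycle-triggered average of an imaging stack
#'
#' For each trigger the nearest frame (by timestamp) defines the
#' alignment index; windows of `n_pre` frames before to `n_post` frames
#' after are averaged frame-wise across cycles. Between `min_cycles`
#' (default 5) and `max_cycles` (default 20) cycles are used; triggers
#' with incomplete windows are dropped.
#'
#' @param stack array T x H x W.
#' @param frame_times frame timestamps, s (length T).
#' @param triggers trigger times, s.
#' @param n_pre,n_post frames before/after the aligned frame.
#' @param min_cycles,max_cycles cycle count bounds.
#' @param rois optional named list of ROI pixel matrices for per-ROI
#'   averaged traces.
#' @return list of class `stack_average`: `frames` (array
#'   (n_pre+n_post+1) x H x W), `rel_index` (-n_pre..n_post), `rel_time`
#'   (s, median frame interval), `n_cycles`, and `roi_traces` (matrix,
#'   when `rois` given).
#' @export
cta_stack <- function(stack, frame_times, triggers, n_pre = 10L,
                      n_post = 30L, min_cycles = 5L, max_cycles = 20L,
                      rois = NULL) {
  n_fr <- dim(stack)[1L]
  if (length(frame_times) != n_fr)
    stop("frame_times length must match the stack")
  centers <- vapply(triggers, function(tt)
    which.min(abs(frame_times - tt)), integer(1))
  ok <- centers - n_pre >= 1L & centers + n_post <= n_fr
  centers <- centers[ok]
  if (length(centers) < min_cycles)
    stop(sprintf("insufficient cycles: %d usable triggers, %d required",
                 length(centers), min_cycles))
  if (length(centers) > max_cycles) centers <- centers[seq_len(max_cycles)]
  rel <- -n_pre:n_post
  acc <- array(0, dim = c(length(rel), dim(stack)[2L], dim(stack)[3L]))
  for (c0 in centers) acc <- acc + stack[c0 + rel, , , drop = FALSE]
  avg <- acc / length(centers)
  dt <- stats::median(diff(frame_times))
  out <- structure(list(frames = avg, rel_index = rel, rel_time = rel * dt,
                        n_cycles = length(centers)),
                   class = "stack_average")
  if (!is.null(rois)) out$roi_traces <- extract_roi_traces(avg, rois)
  out
}

#' Pixel-wise cross-correlation activity map
#'
#' Computes, for every pixel, the zero-lag Pearson correlation of its
#' time series with a reference ROI trace; pixels belonging to cells
#' coactive with the reference light up. Zero-variance pixels are
#' undefined (NA).
#'
#' @param stack array T x H x W (background-subtracted raw fluorescence
#'   by default; pass a dF/F0 stack to correlate dF/F0 pixels instead).
#' @param reference numeric reference trace sampled on the stack's
#'   frames (e.g. a dF/F0 trace of a rhythmic neuron ROI).
#' @param max_lag_frames optional small integer; when > 0 the map holds,
#'   per pixel, the correlation of largest magnitude over lags within
#'   +/- this many frames (default 0 = strict zero lag).
#' @return matrix H x W of correlations in [-1, 1] (class `cc_map`,
#'   attribute `lag` = lag convention used).
#' @export
compute_cc_map <- function(stack, reference, max_lag_frames = 0L) {
  if (inherits(reference, "dff_trace")) reference <- reference$dff
  n_fr <- dim(stack)[1L]
  if (length(reference) != n_fr)
    stop("reference length must match the number of frames")
  H <- dim(stack)[2L]; W <- dim(stack)[3L]
  flat <- matrix(stack, nrow = n_fr)
  cc_at <- function(lag) {
    if (lag == 0L) { px <- flat; rf <- reference }
    else if (lag > 0L) { px <- flat[seq_len(n_fr - lag) + lag, , drop = FALSE]
                         rf <- reference[seq_len(n_fr - lag)] }
    else { l <- -lag; px <- flat[seq_len(n_fr - l), , drop = FALSE]
           rf <- reference[seq_len(n_fr - l) + l] }
    pxc <- sweep(px, 2L, colMeans(px))
    rfc <- rf - mean(rf)
    denom <- sqrt(colSums(pxc^2) * sum(rfc^2))
    cc <- as.numeric(crossprod(pxc, rfc)) / denom
    cc[denom == 0] <- NA_real_
    cc
  }
  cc <- cc_at(0L)
  if (max_lag_frames > 0L) {
    for (lag in setdiff(-max_lag_frames:max_lag_frames, 0L)) {
      cl <- cc_at(lag)
      swap <- !is.na(cl) & (is.na(cc) | abs(cl) > abs(cc))
      cc[swap] <- cl[swap]
    }
  }
  out <- matrix(cc, H, W)
  class(out) <- c("cc_map", class(out))
  attr(out, "lag") <- max_lag_frames
  out
}

#' Classify a cycle-averaged trace as rhythmic
#'
#' A cell is called rhythmic when the peak absolute deviation of its
#' cycle-averaged dF/F0 within the response window exceeds `k` times the
#' SD of the averaged trace over the baseline window. The baseline SD is
#' the yardstick for everything the averaging failed to cancel -
#' recording noise and residuals of arrhythmic spontaneous transients
#' alike - so by default it is taken over all pre-trigger frames
#' (`baseline_window = NULL`), which keeps cells with strong arrhythmic
#' activity from being called rhythmic on the strength of a short,
#' accidentally quiet baseline.
#'
#' @param avg_trace cycle-averaged dF/F0 values.
#' @param rel_time relative time axis of the average, s.
#' @param baseline_window s (relative to the trigger); NULL (default)
#'   uses every frame before the start of the response window.
#' @param response_window s (relative to the trigger).
#' @param k threshold in baseline SDs (default 3).
#' @return list: `rhythmic` (logical), `peak` (signed peak deviation),
#'   `noise_sd` (baseline SD of the averaged trace), `k`.
#' @export
classify_rhythmic <- function(avg_trace, rel_time,
                              baseline_window = NULL,
                              response_window = c(-0.5, 2), k = 3) {
  bi <- if (is.null(baseline_window)) rel_time < response_window[1L]
        else rel_time >= baseline_window[1L] &
             rel_time <= baseline_window[2L]
  if (!any(bi)) stop("baseline window outside the averaged trace")
  ri <- rel_time >= response_window[1L] & rel_time <= response_window[2L]
  b <- mean(avg_trace[bi])
  noise_sd <- stats::sd(avg_trace[bi])
  dev <- avg_trace[ri] - b
  peak <- dev[which.max(abs(dev))]
  list(rhythmic = is.finite(noise_sd) && noise_sd > 0 &&
         abs(peak) > k * noise_sd,
       peak = peak, noise_sd = noise_sd, k = k)
}

#' Detect spontaneous calcium events on a dF/F0 trace
#'
#' Events are maximal runs where dF/F0 exceeds `median + k * robust SD`
#' for at least `min_dur`; a cell is spontaneously active iff it has at
#' least one event.
#'
#' @param dff numeric dF/F0 trace (or `dff_trace`).
#' @param frame_times frame timestamps, s.
#' @param k threshold in robust SDs (default 3).
#' @param min_dur minimum event duration, s.
#' @return list: `events` (data.frame onset_s, offset_s, peak_dff),
#'   `n_events`, `spont_active`.
#' @export
detect_spontaneous_events <- function(dff, frame_times, k = 3,
                                      min_dur = 0.4) {
  if (inherits(dff, "dff_trace")) dff <- dff$dff
  if (!length(dff)) stop("empty trace")
  thr <- stats::median(dff) + k * robust_sd(dff)
  above <- dff > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  onset <- offset <- peak <- numeric(0)
  for (j in sel) {
    i0 <- starts[j]; i1 <- ends[j]
    if (frame_times[i1] - frame_times[i0] +
        stats::median(diff(frame_times)) >= min_dur) {
      onset <- c(onset, frame_times[i0])
      offset <- c(offset, frame_times[i1])
      peak <- c(peak, max(dff[i0:i1]))
    }
  }
  ev <- data.frame(onset_s = onset, offset_s = offset, peak_dff = peak)
  list(events = ev, n_events = nrow(ev), spont_active = nrow(ev) >= 1L)
}

# Peak cycle-averaged deviation of one dF/F0 trace under the observed
# triggers, and under B deterministic circular time shifts of the trace
# (evenly spaced offsets), which destroy any phase relation to the
# triggers while preserving the trace's own autocorrelation. Returns the
# observed peak, the baseline SD of the observed average, and the vector
# of surrogate peaks.
shift_null_peaks <- function(dff, frame_times, triggers, n_pre, n_post,
                             response_window = c(-0.5, 2), B = 99L) {
  n_fr <- length(dff)
  dt <- stats::median(diff(frame_times))
  centers <- vapply(triggers, function(tt)
    which.min(abs(frame_times - tt)), integer(1))
  centers <- centers[centers - n_pre >= 1L & centers + n_post <= n_fr]
  rel <- -n_pre:n_post
  rt <- rel * dt
  bi <- rt < response_window[1L]
  ri <- rt >= response_window[1L] & rt <= response_window[2L]
  peak_stat <- function(x) {
    seg <- vapply(centers, function(c0) x[c0 + rel], numeric(length(rel)))
    m <- rowMeans(seg)
    b <- mean(m[bi])
    dev <- m[ri] - b
    c(peak = dev[which.max(abs(dev))], sd = stats::sd(m[bi]))
  }
  obs <- peak_stat(dff)
  null <- vapply(seq_len(B), function(b) {
    off <- round(n_fr * b / (B + 1))
    peak_stat(dff[((seq_len(n_fr) - 1L + off) %% n_fr) + 1L])[["peak"]]
  }, numeric(1))
  list(peak = obs[["peak"]], noise_sd = obs[["sd"]], null_peaks = null,
       n_cycles = length(centers))
}

#' Classify every ROI of a stack for rhythmicity and spontaneous
#' activity
#'
#' End-to-end per-cell classification: extracts ROI traces, converts to
#' dF/F0, cycle-averages on the supplied triggers, and labels a cell
#' rhythmic when its cycle-averaged response peak both (i) exceeds `k`
#' baseline SDs of the averaged trace (the [classify_rhythmic()]
#' effect-size rule) and (ii) exceeds every one of `B` surrogate peaks
#' obtained by circularly time-shifting the cell's own trace relative to
#' the triggers. The surrogate gate calibrates the decision against the
#' cell's arrhythmic structure: slow spontaneous transients that survive
#' averaging as bumps inflate the surrogate peaks just as they inflate
#' the observed one, so only genuinely phase-locked responses pass.
#' Spontaneous activity is scored with [detect_spontaneous_events()].
#'
#' @param stack array T x H x W (indicator channel).
#' @param frame_times s.
#' @param triggers trigger times, s.
#' @param rois named list of ROI pixel matrices.
#' @param n_pre,n_post averaging window, frames.
#' @param k rhythmicity / event threshold.
#' @param B number of circular-shift surrogates (99 gives a nominal
#'   level of about 1 %).
#' @param min_dur minimum spontaneous-event duration, s.
#' @param min_cycles minimum usable cycles.
#' @param max_cycles unused by the surrogate path but kept for interface
#'   symmetry with [cta_stack()].
#' @return data.frame: roi, rhythmic, cycle_avg_peak, noise_sd,
#'   spont_event_count, spont_active.
#' @export
classify_cells <- function(stack, frame_times, triggers, rois,
                           n_pre = 35L, n_post = 30L, k = 3, B = 99L,
                           min_dur = 0.4, min_cycles = 5L,
                           max_cycles = 20L) {
  traces <- extract_roi_traces(stack, rois)
  res <- lapply(seq_len(ncol(traces)), function(i) {
    dff <- compute_dff(traces[, i])$dff
    sn <- shift_null_peaks(dff, frame_times, triggers, n_pre, n_post,
                           B = B)
    if (sn$n_cycles < min_cycles)
      stop(sprintf("insufficient cycles: %d usable triggers, %d required",
                   sn$n_cycles, min_cycles))
    rhythmic <- is.finite(sn$noise_sd) && sn$noise_sd > 0 &&
      abs(sn$peak) > k * sn$noise_sd &&
      abs(sn$peak) > max(abs(sn$null_peaks))
    ev <- detect_spontaneous_events(dff, frame_times, k = k,
                                    min_dur = min_dur)
    data.frame(roi = colnames(traces)[i], rhythmic = rhythmic,
               cycle_avg_peak = sn$peak, noise_sd = sn$noise_sd,
               spont_event_count = ev$n_events,
               spont_active = ev$spont_active,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
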