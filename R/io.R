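# File formats: trace CSV with a structured header, multi-page TIFF
# stacks with a JSON timing sidecar, ROI masks/polygons, ground-truth
# manifests. One time base throughout: seconds since the first trigger
# pulse of the recording, declared in every header.

#' Write a trace to CSV
#'
#' Columns `time_s, value`; metadata (units, sample rate, holding
#' potential) is carried in `#`-prefixed header lines so a single file
#' is self-describing.
#'
#' @param trace a [glia_trace()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "glia_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# units=%s", trace$units),
               sprintf("# sample_rate_hz=%.10g", trace$sample_rate),
               sprintf("# t0_s=%.10g", trace$t0),
               if (is.finite(trace$v_hold))
                 sprintf("# v_hold_mv=%.10g", trace$v_hold),
               "time_s,value"), con)
  utils::write.table(
    data.frame(time_s = trace_times(trace), value = trace$values),
    con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path CSV path.
#' @param require_v_hold error when TRUE and the header lacks a holding
#'   potential (current CTA needs it).
#' @return a [glia_trace()].
#' @export
read_trace <- function(path, require_v_hold = FALSE) {
  lines <- readLines(path, n = 10L)
  hdr <- grep("^# ", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (!length(m)) return(NA)
    sub(sprintf("^# %s=", key), "", m[1L])
  }
  units <- get_field("units")
  sr <- as.numeric(get_field("sample_rate_hz"))
  t0 <- as.numeric(get_field("t0_s"))
  vh <- as.numeric(get_field("v_hold_mv"))
  if (is.na(sr))
    stop(sprintf("%s: missing required header field sample_rate_hz", path))
  if (require_v_hold && is.na(vh))
    stop(sprintf("%s: missing required header field v_hold_mv", path))
  df <- utils::read.csv(path, comment.char = "#")
  glia_trace(df$value, sr, t0 = if (is.na(t0)) 0 else t0,
             units = if (is.na(units)) "a.u." else units, v_hold = vh)
}

#' Write an image stack as multi-page TIFF plus JSON sidecar
#'
#' One 32-bit float TIFF per channel; frame and trigger timestamps go to
#' a JSON sidecar, which is the single timing authority for the stack.
#' Intensities are scaled to [0, 1] for TIFF storage; the scale is
#' recorded in the sidecar so reading is lossless up to float32.
#'
#' @param stack array T x H x W, or list of such arrays (channels).
#' @param frame_times s.
#' @param trigger_times s.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param pixel_size_um pixel size.
#' @return sidecar path, invisibly.
#' @export
write_stack <- function(stack, frame_times, trigger_times, dir,
                        prefix = "stack", pixel_size_um = 1) {
  if (!is.list(stack)) stack <- list(ch1 = stack)
  if (is.null(names(stack)))
    names(stack) <- paste0("ch", seq_along(stack))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scales <- los <- numeric(length(stack))
  for (ci in seq_along(stack)) {
    arr <- stack[[ci]]
    if (length(frame_times) != dim(arr)[1L])
      stop("frame_times length must match the stack")
    lo <- min(arr); hi <- max(arr)
    scale <- if (hi > lo) hi - lo else 1
    scales[ci] <- scale
    los[ci] <- lo
    pages <- lapply(seq_len(dim(arr)[1L]),
                    function(t) (arr[t, , ] - lo) / scale)
    tiff::writeTIFF(pages, file.path(dir, sprintf("%s_%s.tif", prefix,
                                                  names(stack)[ci])),
                    bits.per.sample = 32L)
  }
  sidecar <- list(frame_times_s = frame_times,
                  trigger_times_s = trigger_times,
                  pixel_size_um = pixel_size_um,
                  channels = names(stack),
                  intensity_offset = los,
                  intensity_scale = scales)
  sc_path <- file.path(dir, sprintf("%s_sidecar.json", prefix))
  jsonlite::write_json(sidecar, sc_path, auto_unbox = TRUE, digits = NA)
  invisible(sc_path)
}

#' Read a stack written by [write_stack()]
#'
#' @param dir directory holding the TIFFs and sidecar.
#' @param prefix file-name prefix used at write time.
#' @return list: per-channel arrays T x H x W, `frame_times`,
#'   `trigger_times`, `pixel_size_um`.
#' @export
read_stack <- function(dir, prefix = "stack") {
  sc <- jsonlite::read_json(file.path(dir, sprintf("%s_sidecar.json",
                                                   prefix)),
                            simplifyVector = TRUE)
  ft <- as.numeric(sc$frame_times_s)
  if (length(ft) > 1L && any(diff(ft) <= 0))
    stop("sidecar frame_times_s must be strictly increasing")
  out <- list()
  for (ci in seq_along(sc$channels)) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("%s_%s.tif", prefix,
                                                   sc$channels[ci])),
                            all = TRUE)
    arr <- array(0, dim = c(length(pages), nrow(pages[[1L]]),
                            ncol(pages[[1L]])))
    for (t in seq_along(pages))
      arr[t, , ] <- pages[[t]] * sc$intensity_scale[ci] +
        sc$intensity_offset[ci]
    out[[sc$channels[ci]]] <- arr
  }
  out$frame_times <- ft
  out$trigger_times <- as.numeric(sc$trigger_times_s)
  out$pixel_size_um <- sc$pixel_size_um
  out
}

#' Read regions of interest
#'
#' Accepts either a 16-bit label-mask TIFF (non-zero label value =
#' cell id) or a JSON file of closed polygons
#' `[{"id": ..., "kind": ..., "vertices": [[row, col], ...]}, ...]` with
#' 0-based pixel vertices. Returns 1-based pixel index matrices.
#'
#' @param path `.tif`/`.tiff` mask or `.json` polygons.
#' @param dim frame dimensions `c(rows, cols)`, required for polygons.
#' @return named list of ROI pixel matrices (columns row, col; 1-based),
#'   with a `kind` attribute per ROI where available.
#' @export
read_rois <- function(path, dim = NULL) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    mask <- tiff::readTIFF(path, as.is = TRUE)
    labels <- sort(setdiff(unique(as.vector(mask)), 0))
    rois <- lapply(labels, function(l) which(mask == l, arr.ind = TRUE))
    names(rois) <- as.character(labels)
    return(rois)
  }
  polys <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(dim)) stop("polygon ROIs need frame `dim`")
  rois <- lapply(polys, function(p) {
    v <- do.call(rbind, lapply(p$vertices, unlist)) + 1  # 0- to 1-based
    px <- polygon_pixels(v[, 1L], v[, 2L], dim)
    attr(px, "kind") <- if (!is.null(p$kind)) p$kind else "unknown"
    px
  })
  names(rois) <- vapply(polys, function(p) as.character(p$id),
                        character(1))
  rois
}

# pixels whose centers fall inside a closed polygon (even-odd rule)
polygon_pixels <- function(rows, cols, dim) {
  rr <- seq_len(dim[1L]); cc <- seq_len(dim[2L])
  grid_r <- rep(rr, times = dim[2L])
  grid_c <- rep(cc, each = dim[1L])
  n <- length(rows)
  inside <- logical(length(grid_r))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((rows[i] > grid_r) != (rows[j] > grid_r)) &
      (grid_c < (cols[j] - cols[i]) * (grid_r - rows[i]) /
         (rows[j] - rows[i]) + cols[i])
    inside <- xor(inside, cross)
    j <- i
  }
  cbind(row = grid_r[inside], col = grid_c[inside])
}

#' Write a ground-truth / result manifest as JSON
#' @param x list to serialize.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
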