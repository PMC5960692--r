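#' Fluorescence image stack
#'
#' Container for a single-trial fluorescence movie: a frames x height x
#' width array plus the acquisition metadata needed downstream.  Pixel
#' coordinates are 0-based `(row, col)`.
#'
#' @param data numeric array, frames x height x width; finite values.
#' @param frame_rate acquisition rate, Hz.
#' @param stim_onset_frame 0-based stimulus onset frame.
#' @param stim_duration stimulus duration, seconds.
#' @param odor,rep,animal optional trial metadata carried into tracesets
#'   extracted from the stack.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, frame_rate, stim_onset_frame,
                        stim_duration = NA_real_, odor = "unknown",
                        rep = 1L, animal = "animal01") {
  if (!is.array(data) || length(dim(data)) != 3L || dim(data)[1L] < 1L)
    stop("`data` must be a frames x height x width array with >= 1 frame")
  if (!all(is.finite(data))) stop("image stack contains non-finite values")
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  structure(list(data = data, frame_rate = frame_rate,
                 stim_onset_frame = as.integer(stim_onset_frame),
                 stim_duration = stim_duration,
                 odor = odor, rep = as.integer(rep), animal = animal),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d frames of %d x %d px, %g Hz (odor %s rep %d)\n",
              d[1], d[2], d[3], x$frame_rate, x$odor, x$rep))
  invisible(x)
}

# 0-based start row/col of a size-s box centred at c (even sizes: the
# centre pixel is the top-left of the central 2x2)
box_start <- function(center, size) center - (size - 1L) %/% 2L

#' Extract the mean trace of a square ROI
#'
#' Averages the `size` x `size` pixel block centred at `(row, col)` in
#' every frame (the standard box average over the centre of a glomerulus).
#' Boxes must lie fully inside the frame; there is no silent clipping.
#'
#' @param stack an [image_stack].
#' @param row,col 0-based centre pixel.
#' @param size box side length in pixels (default 7).
#' @return numeric vector of per-frame means, length `n` frames.
#' @export
extract_box_trace <- function(stack, row, col, size = 7) {
  d <- dim(stack$data)
  size <- as.integer(size)
  if (size < 1L) stop("size must be >= 1")
  r0 <- box_start(as.integer(row), size)
  c0 <- box_start(as.integer(col), size)
  if (r0 < 0L || c0 < 0L || r0 + size > d[2L] || c0 + size > d[3L])
    stop(sprintf("%dx%d box at (%d, %d) exceeds the %d x %d frame",
                 size, size, row, col, d[2L], d[3L]))
  block <- stack$data[, r0 + seq_len(size), c0 + seq_len(size), drop = FALSE]
  rowMeans(block, dims = 1L)
}

#' Extract traces for a list of ROIs into a traceset
#'
#' @param stack an [image_stack].
#' @param rois data.frame with columns `label`, `row`, `col`, `size`
#'   (0-based centers), as read by [read_roi_table()].
#' @return a single-trial [traceset] (`signal_kind = "raw"`).
#' @export
extract_roi_traces <- function(stack, rois) {
  traces <- vapply(seq_len(nrow(rois)), function(i)
    extract_box_trace(stack, rois$row[i], rois$col[i], rois$size[i]),
    numeric(dim(stack$data)[1L]))
  data <- array(t(traces), dim = c(nrow(rois), dim(stack$data)[1L], 1L))
  traceset(data,
           units = data.frame(unit = rois$label, animal = stack$animal,
                              stringsAsFactors = FALSE),
           trials = data.frame(odor = stack$odor, rep = stack$rep,
                               stringsAsFactors = FALSE),
           frame_rate = stack$frame_rate,
           stim_onset_frame = stack$stim_onset_frame,
           stim_duration = stack$stim_duration,
           signal_kind = "raw")
}

#' Spatially bin a stack into tile ROIs
#'
#' Partitions the frame into contiguous `bin_width` x `bin_width` tiles
#' starting at pixel (0, 0); trailing partial tiles are dropped so every
#' tile averages the same number of pixels.  Each tile's per-frame mean
#' becomes one unit; labels encode the 0-based tile coordinates.
#'
#' @param stack an [image_stack].
#' @param bin_width tile side length in pixels (e.g. 4).
#' @return a single-trial [traceset] with one unit per tile.
#' @export
bin_stack <- function(stack, bin_width) {
  d <- dim(stack$data)
  b <- as.integer(bin_width)
  if (b < 1L) stop("bin_width must be >= 1")
  if (b > d[2L] || b > d[3L])
    stop("bin_width larger than the frame dimensions")
  nr <- d[2L] %/% b
  nc <- d[3L] %/% b
  nf <- d[1L]
  data <- array(NA_real_, dim = c(nr * nc, nf, 1L))
  k <- 0L
  for (ci in seq_len(nc)) for (ri in seq_len(nr)) {
    k <- k + 1L
    block <- stack$data[, (ri - 1L) * b + seq_len(b),
                        (ci - 1L) * b + seq_len(b), drop = FALSE]
    data[k, , 1L] <- rowMeans(block, dims = 1L)
  }
  labels <- sprintf("bin_r%02d_c%02d",
                    rep(seq_len(nr) - 1L, times = nc),
                    rep(seq_len(nc) - 1L, each = nr))
  traceset(data,
           units = data.frame(unit = labels, animal = stack$animal,
                              stringsAsFactors = FALSE),
           trials = data.frame(odor = stack$odor, rep = stack$rep,
                               stringsAsFactors = FALSE),
           frame_rate = stack$frame_rate,
           stim_onset_frame = stack$stim_onset_frame,
           stim_duration = stack$stim_duration,
           signal_kind = "raw")
}

#' Keep units whose response exceeds an amplitude threshold
#'
#' A unit is retained iff its maximum single-frame delta-F/F anywhere in
#' the response evaluation window (stimulus onset to the end of the
#' recording), in any trial of any odorant, strictly exceeds
#' `amplitude_threshold`.  Inputs must already be delta-F/F.
#'
#' @param ts a [traceset] with `signal_kind` `"dff"` or `"dff_corrected"`.
#' @param amplitude_threshold delta-F/F threshold (default 0.75).
#' @return the filtered [traceset]; kept/dropped counts are reported via
#'   `message()` and stored in `attr(, "filter_log")`.
#' @export
filter_active_units <- function(ts, amplitude_threshold = 0.75) {
  if (!ts$signal_kind %in% c("dff", "dff_corrected"))
    stop("filter_active_units() expects delta-F/F traces, got signal_kind = '",
         ts$signal_kind, "'")
  eval_frames <- fr_idx(seq.int(ts$stim_onset_frame, n_frames(ts) - 1L))
  peak <- apply(ts$data[, eval_frames, , drop = FALSE], 1L, max, na.rm = TRUE)
  keep <- is.finite(peak) & peak > amplitude_threshold
  message(sprintf("filter_active_units: kept %d / %d units (threshold %g dF/F)",
                  sum(keep), length(keep), amplitude_threshold))
  out <- subset_traceset(ts, units = which(keep))
  attr(out, "filter_log") <- data.frame(unit = ts$units$unit,
                                        peak_dff = peak, kept = keep)
  out
}

#' Read / write image stacks as multi-page TIFF
#'
#' Stacks are stored as 32-bit float TIFF.  Because TIFF float samples are
#' clamped to `[0, 1]` by the writer, values are scaled by `1 / scale`
#' with `scale = max(abs(data))`; the scale and acquisition metadata are
#' stored in a JSON sidecar `<path>.meta.json`.
#'
#' @param stack an [image_stack].
#' @param path TIFF file path.
#' @return `write_stack()` returns `path` invisibly; `read_stack()`
#'   returns an [image_stack].
#' @export
write_stack <- function(stack, path) {
  sc <- max(abs(stack$data), 1e-12)
  pages <- lapply(seq_len(dim(stack$data)[1L]),
                  function(f) stack$data[f, , ] / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(scale = sc, frame_rate = stack$frame_rate,
               stim_onset_frame = stack$stim_onset_frame,
               stim_duration = stack$stim_duration,
               odor = stack$odor, rep = stack$rep, animal = stack$animal)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  else list(scale = 1, frame_rate = 5, stim_onset_frame = 0L,
            stim_duration = NA_real_, odor = "unknown", rep = 1L,
            animal = "animal01")
  data <- array(NA_real_, dim = c(length(pages), nrow(pages[[1L]]),
                                  ncol(pages[[1L]])))
  for (f in seq_along(pages)) data[f, , ] <- pages[[f]] * meta$scale
  image_stack(data, meta$frame_rate, meta$stim_onset_frame,
              meta$stim_duration, meta$odor, meta$rep, meta$animal)
}

#' Read an ROI table from delimited text
#'
#' Expected columns: `label`, `row`, `col`, `size` (and optionally
#' `kind`); coordinates are 0-based box centers.
#'
#' @param path delimited text file (csv/tsv autodetected).
#' @return data.frame of ROI definitions.
#' @export
read_roi_table <- function(path) {
  rois <- as.data.frame(data.table::fread(path))
  need <- c("label", "row", "col", "size")
  if (!all(need %in% names(rois)))
    stop("ROI table needs columns: ", paste(need, collapse = ", "))
  rois
}
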