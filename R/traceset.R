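#' Multi-trial fluorescence trace container
#'
#' A `traceset` holds a population recording as a units x frames x trials
#' array together with unit metadata (animal of origin), trial metadata
#' (odorant label and repetition index) and the acquisition parameters
#' needed to interpret frame indices as times.
#'
#' Frame indexing convention: all frame indices and frame windows in this
#' package are 0-based, and windows of the form `c(a, b)` are half-open
#' `[a, b)`.  Time `t = 0` s is stimulus onset, so frame `f` corresponds to
#' `t = (f - stim_onset_frame) / frame_rate` seconds.
#'
#' @param data numeric array, units x frames x trials.
#' @param units data.frame with columns `unit` (unique identifier) and
#'   `animal`.  Rows correspond to the first array dimension and must be
#'   sorted by (animal, unit); the constructor enforces this canonical
#'   order so that pooled pattern vectors are comparable across objects.
#' @param trials data.frame with columns `odor` (character label) and
#'   `rep` (repetition number within odor).  Rows correspond to the third
#'   array dimension.
#' @param frame_rate acquisition rate in Hz.
#' @param stim_onset_frame 0-based frame index of stimulus onset.
#' @param stim_duration stimulus duration in seconds.
#' @param signal_kind one of `"raw"`, `"dff"`, `"dff_corrected"`.
#'
#' @return An object of class `traceset`.
#' @export
traceset <- function(data, units, trials, frame_rate, stim_onset_frame,
                     stim_duration, signal_kind = "raw") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (units x frames x trials)")
  if (!is.data.frame(units) || !all(c("unit", "animal") %in% names(units)))
    stop("`units` needs columns `unit` and `animal`")
  if (!is.data.frame(trials) || !all(c("odor", "rep") %in% names(trials)))
    stop("`trials` needs columns `odor` and `rep`")
  if (nrow(units) != dim(data)[1L])
    stop("nrow(units) must equal dim(data)[1]")
  if (nrow(trials) != dim(data)[3L])
    stop("nrow(trials) must equal dim(data)[3]")
  if (anyDuplicated(units$unit)) stop("unit identifiers must be unique")
  if (!is.numeric(frame_rate) || frame_rate <= 0) stop("frame_rate must be > 0")
  if (stim_onset_frame < 0 || stim_onset_frame >= dim(data)[2L])
    stop("stim_onset_frame outside recording")
  signal_kind <- match.arg(signal_kind, c("raw", "dff", "dff_corrected"))
  ord <- order(units$animal, units$unit)
  units <- units[ord, , drop = FALSE]
  data <- data[ord, , , drop = FALSE]
  rownames(units) <- NULL
  dimnames(data) <- list(units$unit, NULL, NULL)
  structure(
    list(data = data, units = units, trials = trials,
         frame_rate = frame_rate,
         stim_onset_frame = as.integer(stim_onset_frame),
         stim_duration = stim_duration,
         signal_kind = signal_kind),
    class = "traceset")
}

#' @export
print.traceset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<traceset> %d units, %d frames, %d trials [%s]\n", d[1], d[2], d[3],
    x$signal_kind))
  cat(sprintf("  %g Hz, stimulus onset frame %d, duration %g s\n",
              x$frame_rate, x$stim_onset_frame, x$stim_duration))
  cat(sprintf("  animals: %s\n",
              paste(unique(x$units$animal), collapse = ", ")))
  cat(sprintf("  odorants: %s\n",
              paste(unique(x$trials$odor), collapse = ", ")))
  invisible(x)
}

#' Number of units / frames / trials in a traceset
#' @param ts a [traceset].
#' @return integer count.
#' @export
n_units <- function(ts) dim(ts$data)[1L]

#' @rdname n_units
#' @export
n_frames <- function(ts) dim(ts$data)[2L]

#' @rdname n_units
#' @export
n_trials <- function(ts) dim(ts$data)[3L]

# 0-based frame index -> R array index
fr_idx <- function(frames0) as.integer(frames0) + 1L

# half-open 0-based window c(a, b) -> vector of 0-based frame indices
win_frames <- function(window) {
  window <- as.integer(window)
  if (length(window) != 2L || window[2L] <= window[1L] || window[1L] < 0L)
    stop("window must be half-open c(a, b) with 0 <= a < b")
  seq.int(window[1L], window[2L] - 1L)
}

#' Convert a time window (seconds, stimulus-onset-relative) to frames
#'
#' @param ts a [traceset].
#' @param t_start,t_end window `[t_start, t_end)` in seconds relative to
#'   stimulus onset.
#' @return 0-based half-open frame window `c(a, b)`.
#' @export
time_window <- function(ts, t_start, t_end) {
  a <- ts$stim_onset_frame + as.integer(round(t_start * ts$frame_rate))
  b <- ts$stim_onset_frame + as.integer(round(t_end * ts$frame_rate))
  if (a < 0L || b > n_frames(ts) || b <= a)
    stop("time window outside recording")
  c(a, b)
}

# stimulus frames as 0-based half-open window
stim_window <- function(ts) {
  c(ts$stim_onset_frame,
    ts$stim_onset_frame + as.integer(round(ts$stim_duration * ts$frame_rate)))
}

#' Subset a traceset by units and/or trials
#'
#' @param ts a [traceset].
#' @param units logical/integer/character index into the unit dimension.
#' @param trials logical/integer index into the trial dimension.
#' @return the subset [traceset]; metadata rows follow the data.
#' @export
subset_traceset <- function(ts, units = NULL, trials = NULL) {
  if (!is.null(units)) {
    if (is.character(units)) units <- match(units, ts$units$unit)
    ts$data <- ts$data[units, , , drop = FALSE]
    ts$units <- ts$units[units, , drop = FALSE]
    rownames(ts$units) <- NULL
  }
  if (!is.null(trials)) {
    ts$data <- ts$data[, , trials, drop = FALSE]
    ts$trials <- ts$trials[trials, , drop = FALSE]
    rownames(ts$trials) <- NULL
  }
  ts
}

#' Combine tracesets sharing a time base
#'
#' Binds the trial dimension of tracesets that have identical unit tables
#' and acquisition parameters (e.g. per-trial tracesets extracted from
#' separate image stacks).
#'
#' @param ... tracesets, or a single list of tracesets.
#' @return a [traceset] with the concatenated trials.
#' @export
bind_trials <- function(...) {
  tss <- list(...)
  if (length(tss) == 1L && !inherits(tss[[1L]], "traceset")) tss <- tss[[1L]]
  stopifnot(length(tss) >= 1L)
  ref <- tss[[1L]]
  for (ts in tss[-1L]) {
    if (!identical(ts$units$unit, ref$units$unit) ||
        n_frames(ts) != n_frames(ref) ||
        ts$frame_rate != ref$frame_rate ||
        ts$stim_onset_frame != ref$stim_onset_frame)
      stop("tracesets are not compatible (units or time base differ)")
  }
  data <- array(NA_real_,
                dim = c(n_units(ref), n_frames(ref),
                        sum(vapply(tss, n_trials, 1L))))
  trials <- do.call(rbind, lapply(tss, function(t) t$trials))
  k <- 0L
  for (ts in tss) {
    data[, , k + seq_len(n_trials(ts))] <- ts$data
    k <- k + n_trials(ts)
  }
  rownames(trials) <- NULL
  traceset(data, ref$units, trials, ref$frame_rate, ref$stim_onset_frame,
           ref$stim_duration, ref$signal_kind)
}

#' Write / read a traceset as delimited text
#'
#' The trace table is written in long format with one row per
#' unit x frame x trial (columns `animal`, `unit`, `odor`, `rep`, `frame`,
#' `value`; `frame` is 0-based).  Acquisition metadata go to a JSON
#' sidecar `<path>.meta.json` so that `read_traceset()` can rebuild the
#' object exactly.
#'
#' @param ts a [traceset].
#' @param path output file (CSV).
#' @return `write_traceset()` returns `path` invisibly; `read_traceset()`
#'   returns a [traceset].
#' @export
write_traceset <- function(ts, path) {
  d <- dim(ts$data)
  long <- data.table::data.table(
    animal = rep(ts$units$animal, times = d[2L] * d[3L]),
    unit   = rep(ts$units$unit,   times = d[2L] * d[3L]),
    odor   = rep(ts$trials$odor,  each = d[1L] * d[2L]),
    rep    = rep(ts$trials$rep,   each = d[1L] * d[2L]),
    frame  = rep(rep(0:(d[2L] - 1L), each = d[1L]), times = d[3L]),
    value  = as.vector(ts$data))
  data.table::fwrite(long, path)
  meta <- list(frame_rate = ts$frame_rate,
               stim_onset_frame = ts$stim_onset_frame,
               stim_duration = ts$stim_duration,
               signal_kind = ts$signal_kind)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_traceset
#' @export
read_traceset <- function(path) {
  long <- data.table::fread(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  trials <- unique(long[, c("odor", "rep")])
  data.table::setorder(trials, odor, rep)
  units <- unique(long[, c("unit", "animal")])
  data.table::setorder(units, animal, unit)
  nf <- max(long$frame) + 1L
  data <- array(NA_real_, dim = c(nrow(units), nf, nrow(trials)))
  key_u <- match(long$unit, units$unit)
  key_t <- match(paste(long$odor, long$rep),
                 paste(trials$odor, trials$rep))
  data[cbind(key_u, long$frame + 1L, key_t)] <- long$value
  traceset(data, as.data.frame(units), as.data.frame(trials),
           meta$frame_rate, meta$stim_onset_frame, meta$stim_duration,
           meta$signal_kind)
}
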