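#' delta-F/F parameters
#'
#' @param background_window 0-based half-open frame window `[a, b)` used
#'   to compute the background fluorescence F_B (default frames 10..24,
#'   i.e. the 15 frames before a stimulus starting at frame 25).
#' @return a `dff_params` list.
#' @export
dff_params <- function(background_window = c(10L, 25L)) {
  w <- as.integer(background_window)
  if (length(w) != 2L || w[2L] <= w[1L] || w[1L] < 0L)
    stop("background_window must be half-open c(a, b) with 0 <= a < b")
  structure(list(background_window = w), class = "dff_params")
}

#' Convert raw fluorescence to delta-F/F
#'
#' Per unit and trial, computes `dFF_i = (F_i - F_B) / F_B` where `F_B`
#' is the mean raw fluorescence over the background window.  The mean
#' delta-F/F over the background window is 0 to machine precision.
#' Unit/trial pairs whose `F_B` is zero or non-finite are set to `NA`,
#' flagged in `attr(, "dff_flags")` and reported via `message()`.
#'
#' @param ts a raw [traceset].
#' @param p a [dff_params()].
#' @return a [traceset] with `signal_kind = "dff"`.
#' @export
compute_dff <- function(ts, p = dff_params()) {
  if (ts$signal_kind != "raw")
    stop("compute_dff() expects raw fluorescence, got '", ts$signal_kind, "'")
  w <- p$background_window
  if (w[2L] > ts$stim_onset_frame)
    stop("background window must end at or before stimulus onset")
  if (w[2L] > n_frames(ts)) stop("background window outside recording")
  bg <- fr_idx(win_frames(w))
  flags <- NULL
  for (k in seq_len(n_trials(ts))) {
    fb <- rowMeans(ts$data[, bg, k, drop = FALSE])
    bad <- !is.finite(fb) | fb == 0
    ts$data[, , k] <- ts$data[, , k] / fb - 1
    if (any(bad)) {
      ts$data[bad, , k] <- NA_real_
      flags <- rbind(flags, data.frame(unit = ts$units$unit[bad], trial = k,
                                       reason = "non-positive or non-finite F_B"))
    }
  }
  if (!is.null(flags))
    message(sprintf("compute_dff: excluded %d unit/trial pair(s) with invalid F_B",
                    nrow(flags)))
  ts$signal_kind <- "dff"
  attr(ts, "dff_flags") <- flags
  ts
}

#' Default bleach-fit frame window
#'
#' All frames except the response period (stimulus onset through 5 s
#' after stimulus offset), so that the odor response does not bias the
#' decay estimate.  Use `full = TRUE` to fit over the entire trace.
#'
#' @param ts a [traceset].
#' @param full fit over all frames instead of excluding the response.
#' @return integer vector of 0-based frame indices.
#' @export
bleach_fit_window <- function(ts, full = FALSE) {
  all_f <- seq.int(0L, n_frames(ts) - 1L)
  if (full) return(all_f)
  resp <- seq.int(ts$stim_onset_frame,
                  min(n_frames(ts) - 1L,
                      ts$stim_onset_frame +
                        round((ts$stim_duration + 5) * ts$frame_rate) - 1L))
  setdiff(all_f, resp)
}

#' Fit an exponential bleaching decay to a trace
#'
#' Least-squares fit of `F(t) = a * exp(b * t) + c` (t in frames) over
#' `fit_window`, from a deterministic initialization (`a0` from the
#' first-vs-last values, `b0` from the log-ratio of the first and last
#' thirds, `c0` from the last values).  On non-convergence the fit falls
#' back to a linear model in `exp(b_pin * t)` with `b` pinned to a small
#' negative constant, and the result is flagged.
#'
#' @param trace numeric per-frame series (delta-F/F or intensity change).
#' @param fit_window integer vector of 0-based frame indices (>= 4).
#' @return a `bleach_fit` list: `a`, `b` (per frame), `c`,
#'   `residual_rms`, `fit_window`, `fallback`.
#' @export
fit_bleach <- function(trace, fit_window = seq_along(trace) - 1L) {
  fit_window <- as.integer(fit_window)
  if (length(fit_window) < 4L)
    stop("fit_window must contain at least 4 frames")
  t <- as.numeric(fit_window)
  y <- trace[fr_idx(fit_window)]
  if (any(!is.finite(y))) {
    keep <- is.finite(y)
    t <- t[keep]; y <- y[keep]
    if (length(y) < 4L) stop("fewer than 4 finite frames in fit_window")
  }

  n <- length(y)
  third <- max(2L, n %/% 3L)
  m1 <- mean(y[seq_len(third)]); t1 <- mean(t[seq_len(third)])
  m3 <- mean(y[(n - third + 1L):n]); t3 <- mean(t[(n - third + 1L):n])
  c0 <- mean(y[(n - min(3L, n) + 1L):n])
  d1 <- m1 - c0; d3 <- m3 - c0
  b0 <- if (is.finite(d1) && is.finite(d3) && d1 * d3 > 0)
    max(-1, min(-1e-6, log(abs(d3) / abs(d1)) / (t3 - t1)))
  else -0.001
  a0 <- if (abs(d1) > 0) d1 / exp(b0 * t1) else y[1L] - c0

  try_start <- function(start) tryCatch({
    m <- minpack.lm::nlsLM(y ~ a * exp(b * tt) + c,
                           data = list(y = y, tt = t),
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- stats::coef(m)
    if (!all(is.finite(co))) stop("non-finite coefficients")
    list(a = unname(co["a"]), b = unname(co["b"]), c = unname(co["c"]),
         sse = sum(stats::resid(m)^2), fallback = FALSE)
  }, error = function(e) NULL)
  # two deterministic starts: the decay reading and its mirrored (rising)
  # counterpart; keep whichever converges with the lower SSE
  cands <- Filter(Negate(is.null), list(
    try_start(list(a = a0, b = b0, c = c0)),
    try_start(list(a = (y[1L] - c0), b = -b0, c = c0))))
  fit <- if (length(cands) > 0L) {
    cands[[which.min(vapply(cands, `[[`, numeric(1), "sse"))]]
  } else {
    b_pin <- -1e-4
    lm_fit <- stats::lm(y ~ I(exp(b_pin * t)))
    co <- stats::coef(lm_fit)
    list(a = unname(co[2L]), b = b_pin, c = unname(co[1L]), fallback = TRUE)
  }
  if (fit$b > 0)
    warning("fitted bleach rate b > 0 (fluorescence increases over time; ",
            "possible focus drift)", call. = FALSE)
  resid <- y - (fit$a * exp(fit$b * t) + fit$c)
  structure(list(a = fit$a, b = fit$b, c = fit$c,
                 residual_rms = sqrt(mean(resid^2)),
                 fit_window = fit_window, fallback = fit$fallback),
            class = "bleach_fit")
}

#' Fit bleaching for every unit and trial of a traceset
#'
#' @param ts a delta-F/F [traceset].
#' @param fit_window 0-based frame indices; defaults to
#'   [bleach_fit_window()] (response period excluded).
#' @return data.frame with one row per unit x trial: `unit`, `trial`,
#'   `a`, `b`, `c`, `residual_rms`, `fallback`.
#' @export
fit_bleach_all <- function(ts, fit_window = bleach_fit_window(ts)) {
  grid <- expand.grid(ui = seq_len(n_units(ts)), trial = seq_len(n_trials(ts)))
  rows <- withCallingHandlers(
    lapply(seq_len(nrow(grid)), function(i) {
      f <- fit_bleach(ts$data[grid$ui[i], , grid$trial[i]], fit_window)
      data.frame(unit = ts$units$unit[grid$ui[i]], trial = grid$trial[i],
                 a = f$a, b = f$b, c = f$c, residual_rms = f$residual_rms,
                 fallback = f$fallback)
    }),
    warning = function(w) invokeRestart("muffleWarning"))
  do.call(rbind, rows)
}

#' Subtract fitted bleaching decays from a traceset
#'
#' Subtracts each unit/trial's fitted `a * exp(b * t) + c` at every frame
#' and re-zeroes the background-window mean afterwards.
#'
#' @param ts a delta-F/F [traceset].
#' @param fits data.frame from [fit_bleach_all()]; one row per
#'   unit x trial (missing fits are an error).
#' @param p the [dff_params()] defining the background window to re-zero.
#' @return a [traceset] with `signal_kind = "dff_corrected"`.
#' @export
subtract_bleach <- function(ts, fits, p = dff_params()) {
  t <- seq.int(0L, n_frames(ts) - 1L)
  bg <- fr_idx(win_frames(p$background_window))
  key <- paste(fits$unit, fits$trial)
  for (k in seq_len(n_trials(ts))) {
    rows <- match(paste(ts$units$unit, k), key)
    if (anyNA(rows))
      stop("missing bleach fit for unit(s): ",
           paste(ts$units$unit[is.na(rows)], collapse = ", "),
           " in trial ", k)
    decay <- fits$a[rows] * exp(outer(fits$b[rows], t)) + fits$c[rows]
    corrected <- ts$data[, , k] - decay
    corrected <- corrected - rowMeans(corrected[, bg, drop = FALSE])
    ts$data[, , k] <- corrected
  }
  ts$signal_kind <- "dff_corrected"
  ts
}

#' Full preprocessing: raw -> delta-F/F -> bleach-corrected
#'
#' @param ts a raw [traceset].
#' @param p [dff_params()].
#' @param bleach_correct subtract a fitted exponential decay per
#'   unit/trial (default TRUE).
#' @param fit_window frames used for the bleach fit; see
#'   [bleach_fit_window()].
#' @return a [traceset] (`"dff"` or `"dff_corrected"`); bleach fits, if
#'   any, are attached as `attr(, "bleach_fits")`.
#' @export
preprocess_traces <- function(ts, p = dff_params(), bleach_correct = TRUE,
                              fit_window = NULL) {
  dff <- compute_dff(ts, p)
  if (!bleach_correct) return(dff)
  if (is.null(fit_window)) fit_window <- bleach_fit_window(dff)
  fits <- fit_bleach_all(dff, fit_window)
  out <- subtract_bleach(dff, fits, p)
  attr(out, "bleach_fits") <- fits
  out
}

#' Write bleach fits as delimited text
#' @param fits data.frame from [fit_bleach_all()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bleach_fits <- function(fits, path) {
  data.table::fwrite(fits, path)
  invisible(path)
}
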