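#' Plot a time-resolved correlation matrix
#'
#' Heat map of the Pearson r grid with non-significant cells (p >= alpha)
#' shown in gray, mirroring the conventional display of time-resolved
#' pattern correlation analyses.
#'
#' @param x a [corr_matrix()].
#' @param zlim color range for r.
#' @param ... passed to [graphics::image()].
#' @export
plot.corr_matrix <- function(x, zlim = c(-1, 1), ...) {
  r <- x$r
  r[!x$mask] <- NA
  nf_a <- nrow(r); nf_b <- ncol(r)
  ta <- (seq_len(nf_a) - 1 - x$stim_onset_frame) / x$frame_rate
  tb <- (seq_len(nf_b) - 1 - x$stim_onset_frame) / x$frame_rate
  graphics::image(tb, ta, t(matrix(1, nf_a, nf_b)),
                  col = "gray85", xlab = "time, trial B (s)",
                  ylab = "time, trial A (s)", ...)
  graphics::image(tb, ta, t(r), zlim = zlim,
                  col = grDevices::hcl.colors(64, "RdYlBu", rev = TRUE),
                  add = TRUE)
  invisible(x)
}

#' Plot a correlation trace with its bootstrap envelope
#'
#' @param x a `corr_trace` (see [corr_trace()], [bootstrap_corr()]).
#' @param ... passed to [graphics::plot()].
#' @export
plot.corr_trace <- function(x, ...) {
  t <- (seq_along(x$value) - 1 - x$stim_onset_frame) / x$frame_rate
  graphics::plot(t, x$value, type = "l", xlab = "time (s)",
                 ylab = "mean pattern correlation r", ...)
  if (!is.null(x$boot_sd)) {
    graphics::polygon(c(t, rev(t)),
                      c(x$boot_mean - x$boot_sd,
                        rev(x$boot_mean + x$boot_sd)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(t, x$value)
  }
  invisible(x)
}

#' Plot decoding success by training time with the chance band
#'
#' @param x a `decode_result` (see [sliding_decode()]).
#' @param ... passed to [graphics::plot()].
#' @export
plot.decode_result <- function(x, ...) {
  graphics::plot(x$train_frames, x$stim_avg, type = "l", ylim = c(0, 1),
                 xlab = "training frame", ylab = "stimulus-window success",
                 ...)
  if (!is.null(x$chance_upper)) {
    graphics::polygon(c(x$train_frames, rev(x$train_frames)),
                      c(rep(0, length(x$train_frames)), rev(x$chance_upper)),
                      col = grDevices::adjustcolor("gray", 0.5), border = NA)
    graphics::lines(x$train_frames, x$stim_avg)
    graphics::lines(x$train_frames, x$chance_mean, lty = 2)
  }
  invisible(x)
}
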