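#' Population pattern vectors at a time window
#'
#' For every trial, averages each unit's delta-F/F over the frame window
#' and concatenates the units of the pooled animals in the canonical
#' (animal, unit) order, yielding one pattern vector per trial.
#'
#' @param ts a [traceset].
#' @param t_window 0-based half-open frame window `c(a, b)`.
#' @param pool character vector of animals to pool (default: all).
#' @return matrix units x trials of window-averaged delta-F/F with the
#'   window and pooling recorded in attributes.
#' @export
pattern_at <- function(ts, t_window, pool = NULL) {
  if (is.null(pool)) pool <- unique(ts$units$animal)
  sel <- which(ts$units$animal %in% pool)
  if (length(sel) == 0L) stop("no units from the pooled animals")
  f <- fr_idx(win_frames(t_window))
  if (max(f) > n_frames(ts)) stop("t_window outside recording")
  pat <- apply(ts$data[sel, f, , drop = FALSE], c(1L, 3L), mean)
  dimnames(pat) <- list(ts$units$unit[sel],
                        paste(ts$trials$odor, ts$trials$rep, sep = "_"))
  attr(pat, "window") <- t_window
  attr(pat, "pool") <- pool
  pat
}

# Pearson r matrix between columns of A and columns of B, with two-sided
# p-values from the t transform with n - 2 degrees of freedom (n = rows).
cor_with_p <- function(A, B, alpha = 0.005) {
  n <- nrow(A)
  r <- suppressWarnings(stats::cor(A, B))
  r[!is.finite(r)] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  mask <- !is.na(p) & p < alpha
  list(r = r, p = p, mask = mask, n = n)
}

#' Time-resolved correlation matrix between two trials
#'
#' Computes the Pearson correlation between the single-frame population
#' pattern of trial `trial_a` at time i and that of trial `trial_b` at
#' time j, for all (i, j); two-sided p-values use the t transform with
#' `n_units - 2` degrees of freedom and cells with `p < alpha` form the
#' significance mask.  Cells where a pattern has zero variance are
#' undefined (`NA`) and counted in `n_undefined`.
#'
#' @param ts a delta-F/F [traceset].
#' @param trial_a,trial_b trial indices (rows of `ts$trials`).
#' @param alpha per-cell significance level (default 0.005).
#' @param pool animals to pool (default all).
#' @return object of class `corr_matrix`: `r`, `p`, `mask` (frames_a x
#'   frames_b), `alpha`, `n_units`, `n_undefined`, axis metadata.
#' @export
corr_matrix <- function(ts, trial_a, trial_b, alpha = 0.005, pool = NULL) {
  if (is.null(pool)) pool <- unique(ts$units$animal)
  sel <- which(ts$units$animal %in% pool)
  # observations = units (rows), variables = frames (columns)
  A <- ts$data[sel, , trial_a]
  B <- ts$data[sel, , trial_b]
  cw <- cor_with_p(A, B, alpha)
  structure(list(r = cw$r, p = cw$p, mask = cw$mask, alpha = alpha,
                 n_units = cw$n, n_undefined = sum(is.na(cw$r)),
                 trial_a = ts$trials[trial_a, ], trial_b = ts$trials[trial_b, ],
                 frame_rate = ts$frame_rate,
                 stim_onset_frame = ts$stim_onset_frame),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("<corr_matrix> %d x %d frames, %d units, alpha = %g (%d undefined)\n",
              nrow(x$r), ncol(x$r), x$n_units, x$alpha, x$n_undefined))
  invisible(x)
}

#' Correlation trace against a reference window
#'
#' Averages the correlation-matrix rows belonging to `ref_window` (frames
#' on the first trial's axis), yielding the mean correlation of that
#' reference pattern with the second trial's pattern at every time point.
#' Undefined cells are excluded from the average; their count is kept in
#' `n_excluded`.
#'
#' @param m a [corr_matrix()].
#' @param ref_window 0-based half-open frame window on axis A.
#' @return object of class `corr_trace`: `value` (length frames_b),
#'   `ref_window`, `n_excluded`.
#' @export
corr_trace <- function(m, ref_window) {
  rows <- fr_idx(win_frames(ref_window))
  if (max(rows) > nrow(m$r)) stop("ref_window outside axis A")
  block <- m$r[rows, , drop = FALSE]
  structure(list(value = colMeans(block, na.rm = TRUE),
                 ref_window = ref_window,
                 n_excluded = sum(is.na(block)),
                 frame_rate = m$frame_rate,
                 stim_onset_frame = m$stim_onset_frame),
            class = "corr_trace")
}

#' Bootstrap envelope for a correlation trace
#'
#' Resamples animals with replacement `n_boot` times; each replicate
#' rebuilds the pooled population (duplicated animals contribute their
#' units twice), recomputes the correlation of the reference-window
#' pattern of trial `trial_a` with trial `trial_b` at every time point,
#' and the per-time SD over replicates forms the envelope.
#'
#' @param ts a delta-F/F [traceset].
#' @param trial_a,trial_b trial indices.
#' @param ref_window 0-based half-open frame window on trial_a's axis.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return a `corr_trace` with additional fields `boot_mean`, `boot_sd`
#'   and `n_boot`; `value` holds the full-data trace.
#' @export
bootstrap_corr <- function(ts, trial_a, trial_b, ref_window,
                           n_boot = 1000, seed = 1L) {
  animals <- unique(ts$units$animal)
  if (length(animals) < 1L) stop("need at least one animal")
  m <- corr_matrix(ts, trial_a, trial_b)
  base <- corr_trace(m, ref_window)

  ref <- fr_idx(win_frames(ref_window))
  A <- t(ts$data[, , trial_a])   # frames x units
  B <- t(ts$data[, , trial_b])
  by_animal <- split(seq_len(n_units(ts)), ts$units$animal)
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, n_frames(ts))
  for (b in seq_len(n_boot)) {
    samp <- sample(animals, length(animals), replace = TRUE)
    cols <- unlist(by_animal[samp], use.names = FALSE)
    # observations = resampled units, variables = frames
    r <- suppressWarnings(stats::cor(t(A[ref, cols, drop = FALSE]),
                                     t(B[, cols, drop = FALSE])))
    reps[b, ] <- colMeans(r, na.rm = TRUE)
  }
  base$boot_mean <- colMeans(reps, na.rm = TRUE)
  base$boot_sd <- apply(reps, 2L, stats::sd, na.rm = TRUE)
  base$n_boot <- n_boot
  base
}

#' Pairwise odor/post-odor pattern correlation tables
#'
#' Builds the three trial-by-trial Pearson correlation tables of the
#' named pattern windows: odor pattern vs odor pattern, post-odor vs
#' post-odor, and odor vs post-odor.  The diagonal of the odor-vs-post
#' table quantifies how similar each stimulation's post-odor pattern is
#' to its own odor pattern.
#'
#' @param ts a delta-F/F [traceset].
#' @param odor_window,post_window 0-based half-open frame windows;
#'   defaults are t = 1..2 s and t = 15..16 s relative to stimulus onset
#'   (the latter is 5 s after offset for a 10-s stimulus).
#' @param pool animals to pool (default all).
#' @return object of class `pairwise_corr`: matrices `odor_vs_odor`,
#'   `post_vs_post`, `odor_vs_post` (trials x trials, labelled
#'   `odor_rep`), plus the windows used.
#' @export
pairwise_window_corr <- function(ts, odor_window = NULL, post_window = NULL,
                                 pool = NULL) {
  if (n_trials(ts) < 2L) stop("need at least 2 odorant x trial combinations")
  if (is.null(odor_window)) odor_window <- time_window(ts, 1, 2)
  if (is.null(post_window))
    post_window <- time_window(ts, ts$stim_duration + 5, ts$stim_duration + 6)
  P_odor <- pattern_at(ts, odor_window, pool)
  P_post <- pattern_at(ts, post_window, pool)
  structure(list(
    odor_vs_odor = suppressWarnings(stats::cor(P_odor)),
    post_vs_post = suppressWarnings(stats::cor(P_post)),
    odor_vs_post = suppressWarnings(stats::cor(P_odor, P_post)),
    odor_window = odor_window, post_window = post_window,
    trials = ts$trials), class = "pairwise_corr")
}

#' @export
print.pairwise_corr <- function(x, ...) {
  cat("<pairwise_corr> odor-vs-post diagonal:\n")
  print(round(diag(x$odor_vs_post), 3))
  invisible(x)
}

#' Write a correlation matrix as a delimited grid plus JSON sidecar
#'
#' @param m a [corr_matrix()].
#' @param path output CSV path for the r grid; the p grid goes to
#'   `<path>.p.csv` and axes/alpha/provenance to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_corr_matrix <- function(m, path) {
  data.table::fwrite(as.data.frame(m$r), path, col.names = FALSE)
  data.table::fwrite(as.data.frame(m$p), paste0(path, ".p.csv"),
                     col.names = FALSE)
  meta <- list(alpha = m$alpha, n_units = m$n_units,
               n_undefined = m$n_undefined,
               trial_a = as.list(m$trial_a), trial_b = as.list(m$trial_b),
               frame_rate = m$frame_rate,
               stim_onset_frame = m$stim_onset_frame)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
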