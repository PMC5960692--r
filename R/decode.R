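#' Configuration for sliding-window population decoding
#'
#' @param nu nu parameter of the nu-SVM (default 0.9).  When a
#'   cross-validation fold has unbalanced class counts that make this nu
#'   infeasible for some one-vs-one subproblem, nu is clipped per fold to
#'   the largest feasible value and the result is flagged.
#' @param train_window_width width in seconds of the averaged training
#'   window (default 2).
#' @param eval_window 0-based half-open frame window over which the
#'   summary classification success is averaged; `NULL` (default) means
#'   the stimulus window.
#' @param n_permutations label permutations for the chance band
#'   (default 250).
#' @param ci_level upper percentile of the permutation distribution used
#'   as the significance bound (default 95).
#' @param feature_scaling `"zscore"` (per-unit, fitted on training
#'   samples only; default) or `"none"`.
#' @param kernel SVM kernel (default `"linear"`).
#' @param cv `"rep"` (default): leave-one-repetition-out, holding out one
#'   whole trial of every class per fold so folds stay class-balanced;
#'   `"resub"`: train and test on all trials (resubstitution).
#' @param train_step stride in frames between evaluated training times in
#'   [sliding_decode()] (default 1).
#' @param seed RNG seed for the permutation draw.
#' @return a `decode_config` list.
#' @export
decode_config <- function(nu = 0.9, train_window_width = 2,
                          eval_window = NULL, n_permutations = 250,
                          ci_level = 95, feature_scaling = c("zscore", "none"),
                          kernel = "linear", cv = c("rep", "resub"),
                          train_step = 1L, seed = 1L) {
  if (nu <= 0 || nu > 1) stop("nu must be in (0, 1]")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (train_window_width <= 0) stop("train_window_width must be > 0")
  structure(list(nu = nu, train_window_width = train_window_width,
                 eval_window = eval_window,
                 n_permutations = as.integer(n_permutations),
                 ci_level = ci_level,
                 feature_scaling = match.arg(feature_scaling),
                 kernel = kernel, cv = match.arg(cv),
                 train_step = as.integer(train_step),
                 seed = as.integer(seed)),
            class = "decode_config")
}

#' Windowed population features for every trial
#'
#' One sample per trial: each unit's delta-F/F averaged over
#' `[t, t + width)` seconds worth of frames, labelled by odorant.
#'
#' @param ts a delta-F/F [traceset].
#' @param t_frame 0-based frame at which the window starts.
#' @param width window width in seconds.
#' @return list: `x` (trials x units feature matrix), `y` (factor of
#'   odorant labels), `frames` (0-based frames averaged).
#' @export
features_at <- function(ts, t_frame, width) {
  wf <- max(1L, as.integer(round(width * ts$frame_rate)))
  frames <- seq.int(t_frame, t_frame + wf - 1L)
  if (t_frame < 0L || max(frames) > n_frames(ts) - 1L)
    stop("feature window [", t_frame, ", ", t_frame + wf,
         ") exceeds the recording")
  x <- t(apply(ts$data[, fr_idx(frames), , drop = FALSE], c(1L, 3L), mean))
  colnames(x) <- ts$units$unit
  list(x = x, y = factor(ts$trials$odor), frames = frames)
}

# largest feasible nu for a one-vs-one nu-SVC given class counts
nu_max_feasible <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) < 2L) return(1)
  pairs <- utils::combn(as.numeric(counts), 2L)
  min(2 * pmin(pairs[1L, ], pairs[2L, ]) / (pairs[1L, ] + pairs[2L, ]))
}

# fit nu-SVM with per-fold nu clipping; returns model + scaling + flag
fit_nusvm <- function(x, y, cfg) {
  center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  if (cfg$feature_scaling == "zscore") {
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
    x <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  }
  numax <- nu_max_feasible(table(droplevels(y)))
  nu_eff <- if (cfg$nu <= numax) cfg$nu else 0.99 * numax
  model <- e1071::svm(x, droplevels(y), type = "nu-classification",
                      nu = nu_eff, kernel = cfg$kernel, scale = FALSE)
  list(model = model, center = center, scale = scale,
       nu_clipped = nu_eff < cfg$nu, nu_eff = nu_eff)
}

predict_frames <- function(fit, ts, trial, test_frames) {
  z <- t(ts$data[, fr_idx(test_frames), trial, drop = FALSE][, , 1L])
  colnames(z) <- ts$units$unit
  z <- sweep(sweep(z, 2L, fit$center), 2L, fit$scale, "/")
  as.character(stats::predict(fit$model, z))
}

# cross-validation folds: list of list(train = trial idx, test = trial idx)
decode_folds <- function(ts, cfg) {
  if (cfg$cv == "resub")
    return(list(list(train = seq_len(n_trials(ts)),
                     test = seq_len(n_trials(ts)))))
  reps <- sort(unique(ts$trials$rep))
  # classes represented by a single trial stay in every training set and
  # are evaluated by resubstitution (flagged on the result)
  counts <- table(ts$trials$odor)
  singles <- which(ts$trials$odor %in% names(counts)[counts == 1L])
  lapply(reps, function(r) {
    test <- which(ts$trials$rep == r)
    train <- union(which(ts$trials$rep != r), singles)
    list(train = train, test = test)
  })
}

#' Decoding success over time for one training time
#'
#' Trains a multi-class (one-vs-one) nu-SVM on the window-averaged
#' population patterns at `train_frame` and evaluates, for every test
#' time point, the fraction of held-out trials whose single-frame
#' pattern is classified as the correct odorant.  Cross-validation holds
#' out one repetition of every odorant per fold, so success at test
#' times inside the training window still reflects held-out
#' generalization (use `cv = "resub"` in the config for resubstitution).
#'
#' @param ts a delta-F/F [traceset] with >= 2 odorant classes.
#' @param train_frame 0-based frame at which the training window starts.
#' @param cfg a [decode_config()].
#' @param test_frames 0-based frames to evaluate (default: all).
#' @param score_trials trial indices over which classification success is
#'   scored (default: all trials).  All trials are always used for
#'   training; restricting scoring to the odor trials (excluding the
#'   solvent class) measures odor-identity decoding specifically, since a
#'   silent blank class is identifiable at all times and otherwise adds a
#'   constant ~1/k success floor.
#' @return numeric vector of classification success per test frame, with
#'   attributes `nu_clipped`, `resub_classes`.
#' @export
decode_from <- function(ts, train_frame, cfg = decode_config(),
                        test_frames = NULL, score_trials = NULL) {
  if (length(unique(ts$trials$odor)) < 2L)
    stop("decoding needs at least 2 odorant classes")
  if (is.null(test_frames)) test_frames <- seq.int(0L, n_frames(ts) - 1L)
  if (is.null(score_trials)) score_trials <- seq_len(n_trials(ts))
  folds <- decode_folds(ts, cfg)
  feats <- features_at(ts, train_frame, cfg$train_window_width)
  correct <- numeric(length(test_frames))
  total <- 0L
  clipped <- FALSE
  for (fold in folds) {
    fit <- fit_nusvm(feats$x[fold$train, , drop = FALSE],
                     feats$y[fold$train], cfg)
    clipped <- clipped || fit$nu_clipped
    for (trial in intersect(fold$test, score_trials)) {
      pred <- predict_frames(fit, ts, trial, test_frames)
      correct <- correct + (pred == ts$trials$odor[trial])
      total <- total + 1L
    }
  }
  out <- correct / total
  attr(out, "nu_clipped") <- clipped
  counts <- table(ts$trials$odor)
  attr(out, "resub_classes") <- names(counts)[counts == 1L]
  out
}

#' Sliding-window decoding with stimulus-window summary
#'
#' Runs [decode_from()] for every training time and summarises each
#' training time by the mean classification success over the evaluation
#' window (by default the 10-s stimulus window).
#'
#' @param ts a delta-F/F [traceset].
#' @param cfg a [decode_config()].
#' @param train_frames 0-based training window start frames (default:
#'   every `train_step`-th frame for which the window fits).
#' @param test_frames frames at which success curves are evaluated
#'   (default: all frames).
#' @param score_trials trials scored for success (see [decode_from()]).
#' @return object of class `decode_result`: `success` (train times x
#'   test frames), `stim_avg` (per train time), `train_frames`,
#'   `test_frames`, `eval_window`, `config`; `chance_mean`/`chance_upper`
#'   are `NULL` until filled by [permutation_chance()] /
#'   [decode_analysis()].
#' @export
sliding_decode <- function(ts, cfg = decode_config(), train_frames = NULL,
                           test_frames = NULL, score_trials = NULL) {
  wf <- max(1L, as.integer(round(cfg$train_window_width * ts$frame_rate)))
  if (is.null(train_frames))
    train_frames <- seq.int(0L, n_frames(ts) - wf, by = cfg$train_step)
  if (is.null(test_frames)) test_frames <- seq.int(0L, n_frames(ts) - 1L)
  eval_window <- if (is.null(cfg$eval_window)) stim_window(ts) else cfg$eval_window
  eval_frames <- win_frames(eval_window)
  if (!all(eval_frames %in% test_frames))
    test_frames <- sort(union(test_frames, eval_frames))

  success <- matrix(NA_real_, length(train_frames), length(test_frames),
                    dimnames = list(train_frames, test_frames))
  for (i in seq_along(train_frames))
    success[i, ] <- decode_from(ts, train_frames[i], cfg, test_frames,
                                score_trials)
  stim_avg <- rowMeans(success[, match(eval_frames, test_frames),
                               drop = FALSE])
  structure(list(success = success, stim_avg = stim_avg,
                 train_frames = train_frames, test_frames = test_frames,
                 eval_window = eval_window, config = cfg,
                 n_units = n_units(ts),
                 chance_mean = NULL, chance_upper = NULL),
            class = "decode_result")
}

#' Permutation chance band for sliding decoding
#'
#' Shuffles the odorant labels across whole trials, reruns the identical
#' sliding-decode pipeline, and collects the stimulus-window average
#' success of every permutation.  The per-train-time mean is the chance
#' level and the `ci_level` percentile (default 95th) is the significance
#' bound.
#'
#' @param ts a delta-F/F [traceset].
#' @param cfg a [decode_config()].
#' @param train_frames training times to evaluate (default as in
#'   [sliding_decode()]).
#' @param score_trials trials scored for success (see [decode_from()]).
#' @return list: `chance_mean`, `chance_upper` (per train time),
#'   `stim_avg` (permutations x train times matrix), `n_permutations`.
#' @export
permutation_chance <- function(ts, cfg = decode_config(),
                               train_frames = NULL, score_trials = NULL) {
  wf <- max(1L, as.integer(round(cfg$train_window_width * ts$frame_rate)))
  if (is.null(train_frames))
    train_frames <- seq.int(0L, n_frames(ts) - wf, by = cfg$train_step)
  eval_window <- if (is.null(cfg$eval_window)) stim_window(ts) else cfg$eval_window
  eval_frames <- win_frames(eval_window)

  n_arrangements <- exp(lfactorial(n_trials(ts)) -
                          sum(lfactorial(table(ts$trials$odor))))
  if (n_arrangements < cfg$n_permutations)
    message(sprintf(paste0(
      "permutation_chance: only %.0f distinct label arrangements; ",
      "sampling %d permutations with replacement"),
      n_arrangements, cfg$n_permutations))

  set.seed(cfg$seed)
  perms <- matrix(NA_real_, cfg$n_permutations, length(train_frames))
  for (pidx in seq_len(cfg$n_permutations)) {
    ts_p <- ts
    ts_p$trials$odor <- sample(ts$trials$odor)
    for (i in seq_along(train_frames))
      perms[pidx, i] <- mean(decode_from(ts_p, train_frames[i], cfg,
                                         eval_frames, score_trials))
  }
  list(chance_mean = colMeans(perms),
       chance_upper = apply(perms, 2L, stats::quantile,
                            probs = cfg$ci_level / 100),
       stim_avg = perms, n_permutations = cfg$n_permutations,
       train_frames = train_frames)
}

#' Sliding decoding plus permutation chance band
#'
#' Convenience wrapper running [sliding_decode()] and
#' [permutation_chance()] with the same configuration and training times.
#'
#' @inheritParams sliding_decode
#' @return a `decode_result` with `chance_mean` and `chance_upper` filled.
#' @export
decode_analysis <- function(ts, cfg = decode_config(), train_frames = NULL,
                            score_trials = NULL) {
  res <- sliding_decode(ts, cfg, train_frames, score_trials = score_trials)
  ch <- permutation_chance(ts, cfg, res$train_frames, score_trials)
  res$chance_mean <- ch$chance_mean
  res$chance_upper <- ch$chance_upper
  res
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> %d train times, %d units, nu = %g\n",
              length(x$train_frames), x$n_units, x$config$nu))
  cat(sprintf("  stimulus-window success: max %.3f (train frame %s)\n",
              max(x$stim_avg), names(which.max(x$stim_avg))))
  if (!is.null(x$chance_upper))
    cat(sprintf("  train times above chance bound: %d / %d\n",
                sum(x$stim_avg > x$chance_upper), length(x$stim_avg)))
  invisible(x)
}

#' Write a decode result as delimited grids plus JSON provenance
#'
#' @param res a `decode_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_decode_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(as.data.frame(res$success),
                     file.path(dir, "success.csv"))
  summary <- data.frame(train_frame = res$train_frames,
                        stim_avg = res$stim_avg)
  if (!is.null(res$chance_mean)) {
    summary$chance_mean <- res$chance_mean
    summary$chance_upper <- res$chance_upper
  }
  data.table::fwrite(summary, file.path(dir, "stim_avg.csv"))
  prov <- list(config = unclass(res$config), n_units = res$n_units,
               eval_window = res$eval_window)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
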