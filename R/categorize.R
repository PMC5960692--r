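#' Configuration for response-dynamics categorization
#'
#' Responses are sorted into *on* (responding only during the stimulus),
#' *off* (responding only after stimulus offset), *prolonged* (sustained
#' beyond offset) or *none*, using a threshold of
#' `threshold_multiplier x SD` of the pre-stimulus signal (2.57 SD
#' corresponds to a one-sided significance of p < 0.005) and a 1/e decay
#' criterion evaluated within `post_eval_delay` seconds after offset.
#'
#' @param threshold_multiplier response threshold in pre-stimulus SD
#'   units (default 2.57).
#' @param decay_fraction fraction of the stimulus-window maximum below
#'   which a response counts as decayed (default `exp(-1)`, i.e. 37%).
#' @param post_eval_delay seconds after odor offset within which the
#'   decay criterion is evaluated, and at which the off criterion is
#'   centred (default 5).
#' @param pre_window 0-based half-open frame window for the pre-stimulus
#'   SD (default the delta-F/F background window, frames 10..24).
#' @param off_eval_width width in seconds of the off-response evaluation
#'   window centred at offset + `post_eval_delay` (default 1).
#' @param min_frames minimum number of consecutive frames above threshold
#'   that counts as a stimulus-window crossing (default 2; a single
#'   supra-threshold frame in a 50-frame stimulus window is expected by
#'   chance at the 0.005 level, see the package vignette).
#' @param decline_rule `"any_frame"` (default): the response is *on* if
#'   any frame within `post_eval_delay` after offset falls below
#'   `decay_fraction` of the maximum; `"endpoint"`: only the value at
#'   offset + `post_eval_delay` is checked.
#' @param off_rule `"window_mean"` (default): the off criterion compares
#'   the mean of the off evaluation window with the threshold;
#'   `"any_frame"`: any supra-threshold frame within `post_eval_delay`
#'   after offset counts.
#' @return a `categorize_config` list.
#' @export
categorize_config <- function(threshold_multiplier = 2.57,
                              decay_fraction = exp(-1),
                              post_eval_delay = 5,
                              pre_window = c(10L, 25L),
                              off_eval_width = 1,
                              min_frames = 2L,
                              decline_rule = c("any_frame", "endpoint"),
                              off_rule = c("window_mean", "any_frame")) {
  if (threshold_multiplier <= 0) stop("threshold_multiplier must be > 0")
  if (decay_fraction <= 0 || decay_fraction >= 1)
    stop("decay_fraction must be in (0, 1)")
  if (post_eval_delay <= 0) stop("post_eval_delay must be > 0")
  if (min_frames < 1L) stop("min_frames must be >= 1")
  structure(list(threshold_multiplier = threshold_multiplier,
                 decay_fraction = decay_fraction,
                 post_eval_delay = post_eval_delay,
                 pre_window = as.integer(pre_window),
                 off_eval_width = off_eval_width,
                 min_frames = as.integer(min_frames),
                 decline_rule = match.arg(decline_rule),
                 off_rule = match.arg(off_rule)),
            class = "categorize_config")
}

#' Response threshold from the pre-stimulus signal
#'
#' `threshold_multiplier` times the sample SD (n - 1 denominator) of the
#' trace over the pre-stimulus window.  A zero-variance pre-stimulus
#' segment yields threshold 0 with a warning (any positive deflection
#' then counts as a crossing).
#'
#' @param trace numeric per-frame series.
#' @param cfg a [categorize_config()].
#' @return threshold in the units of `trace`.
#' @export
response_threshold <- function(trace, cfg = categorize_config()) {
  pre <- trace[fr_idx(win_frames(cfg$pre_window))]
  if (length(pre) < 2L) stop("pre_window must contain at least 2 frames")
  s <- stats::sd(pre)
  if (!is.finite(s)) return(NA_real_)
  if (s == 0) {
    warning("zero pre-stimulus variance: threshold is 0, any positive ",
            "deflection counts as a crossing", call. = FALSE)
    return(0)
  }
  cfg$threshold_multiplier * s
}

# does `x` contain a run of >= k values that are TRUE?
has_run <- function(x, k) {
  x[is.na(x)] <- FALSE
  if (k <= 1L) return(any(x))
  r <- rle(x)
  any(r$values & r$lengths >= k)
}

#' Categorize a single response trace
#'
#' Decision tree: (i) if the trace crosses the response threshold during
#' the stimulus window, it is *on* when it falls below
#' `decay_fraction x max` within `post_eval_delay` seconds after offset
#' and *prolonged* otherwise; (ii) with no stimulus-window crossing it is
#' *off* when the off evaluation window (centred `post_eval_delay` after
#' offset) exceeds the threshold; (iii) otherwise *none*.  Thresholds are
#' one-sided positive: purely negative (inhibitory) deflections are
#' labelled *none*.
#'
#' @param trace numeric per-frame series (delta-F/F).
#' @param stim_win 0-based half-open frame window `c(onset, offset)` of
#'   the stimulus.
#' @param cfg a [categorize_config()].
#' @param frame_rate acquisition rate, Hz (to convert the second-valued
#'   config fields to frames).
#' @return list: `label` (one of `"on"`, `"off"`, `"prolonged"`,
#'   `"none"`), `threshold`, `max_stim`, `post_value` (mean delta-F/F in
#'   the off evaluation window), `ratio` (`post_value / max_stim`),
#'   `flagged` (TRUE when NaN frames forced the label to *none*).
#' @export
categorize_response <- function(trace, stim_win, cfg = categorize_config(),
                                frame_rate) {
  thr <- suppressWarnings(response_threshold(trace, cfg))
  onset <- stim_win[1L]; offset <- stim_win[2L]
  delay_f <- as.integer(round(cfg$post_eval_delay * frame_rate))
  width_f <- max(1L, as.integer(round(cfg$off_eval_width * frame_rate)))
  dip_frames <- seq.int(offset + 1L, min(offset + delay_f, length(trace) - 1L))
  center <- offset + delay_f
  off_frames <- seq.int(center - (width_f - 1L) %/% 2L,
                        center + width_f %/% 2L)
  off_frames <- off_frames[off_frames <= length(trace) - 1L]
  stim_frames <- win_frames(stim_win)

  vals_stim <- trace[fr_idx(stim_frames)]
  vals_dip <- trace[fr_idx(dip_frames)]
  vals_off <- trace[fr_idx(off_frames)]
  if (!is.finite(thr) || anyNA(vals_stim) || anyNA(vals_dip) || anyNA(vals_off))
    return(list(label = "none", threshold = thr, max_stim = NA_real_,
                post_value = NA_real_, ratio = NA_real_, flagged = TRUE))

  post_value <- mean(vals_off)
  if (has_run(vals_stim > thr, cfg$min_frames)) {
    m <- max(vals_stim)
    declined <- if (cfg$decline_rule == "any_frame")
      any(vals_dip < cfg$decay_fraction * m)
    else
      trace[fr_idx(min(center, length(trace) - 1L))] < cfg$decay_fraction * m
    label <- if (declined) "on" else "prolonged"
    return(list(label = label, threshold = thr, max_stim = m,
                post_value = post_value, ratio = post_value / m,
                flagged = FALSE))
  }
  is_off <- if (cfg$off_rule == "window_mean") post_value > thr
  else has_run(vals_dip > thr, cfg$min_frames)
  list(label = if (is_off) "off" else "none", threshold = thr,
       max_stim = max(vals_stim), post_value = post_value,
       ratio = NA_real_, flagged = FALSE)
}

#' Categorize every unit x odor x trial of a traceset
#'
#' Applies [categorize_response()] per trial, then aggregates a
#' unit x odor label as the majority across trials, breaking ties toward
#' the weaker claim (none < on < off < prolonged).
#'
#' @param ts a delta-F/F [traceset].
#' @param cfg a [categorize_config()].
#' @return object of class `category_result`: list with `per_trial`
#'   (one row per unit x odor x trial) and `per_unit` (majority label per
#'   unit x odor) data.frames.
#' @export
categorize_traceset <- function(ts, cfg = categorize_config()) {
  if (!ts$signal_kind %in% c("dff", "dff_corrected"))
    stop("categorize_traceset() expects delta-F/F traces")
  sw <- stim_window(ts)
  n_zero_var <- 0L
  rows <- vector("list", n_units(ts) * n_trials(ts))
  i <- 0L
  for (k in seq_len(n_trials(ts))) {
    for (ui in seq_len(n_units(ts))) {
      res <- withCallingHandlers(
        categorize_response(ts$data[ui, , k], sw, cfg, ts$frame_rate),
        warning = function(w) {
          if (grepl("zero pre-stimulus variance", conditionMessage(w)))
            n_zero_var <<- n_zero_var + 1L
          invokeRestart("muffleWarning")
        })
      i <- i + 1L
      rows[[i]] <- data.frame(
        animal = ts$units$animal[ui], unit = ts$units$unit[ui],
        odor = ts$trials$odor[k], rep = ts$trials$rep[k], trial = k,
        label = res$label, threshold = res$threshold,
        max_stim = res$max_stim, post_value = res$post_value,
        ratio = res$ratio, flagged = res$flagged,
        stringsAsFactors = FALSE)
    }
  }
  per_trial <- do.call(rbind, rows)
  if (n_zero_var > 0L)
    message(sprintf(
      "categorize_traceset: %d trace(s) had zero pre-stimulus variance (threshold 0)",
      n_zero_var))

  strength <- c(none = 0L, on = 1L, off = 2L, prolonged = 3L)
  agg <- stats::aggregate(label ~ animal + unit + odor, data = per_trial,
                          FUN = function(lbl) {
                            tab <- table(lbl)
                            winners <- names(tab)[tab == max(tab)]
                            winners[which.min(strength[winners])]
                          })
  structure(list(per_trial = per_trial, per_unit = agg),
            class = "category_result")
}

#' @export
print.category_result <- function(x, ...) {
  cat("<category_result>\n  per-unit labels:\n")
  print(table(x$per_unit$label))
  invisible(x)
}

#' Fractions of responding units per category
#'
#' Within each group (animal, odor, or any metadata column of the
#' per-unit table), computes the fraction of *responding* entries
#' (label != none) in each of the on/off/prolonged categories; the three
#' fractions sum to 1 per group.  Groups with no responding entries are
#' excluded from the summary with a message.
#'
#' @param res a `category_result` from [categorize_traceset()], or its
#'   `per_unit` data.frame.
#' @param group_by grouping column, e.g. `"animal"` or `"odor"`.
#' @return list with `fractions` (long data.frame: group, category,
#'   fraction, n_responding) and `summary` (per category: median and
#'   quartiles across groups).
#' @export
category_fractions <- function(res, group_by = "animal") {
  tab <- if (inherits(res, "category_result")) res$per_unit else res
  if (nrow(tab) == 0L) stop("empty category results")
  if (!group_by %in% names(tab))
    stop("grouping column '", group_by, "' not present")
  cats <- c("on", "off", "prolonged")
  groups <- split(tab, tab[[group_by]])
  out <- lapply(names(groups), function(g) {
    lbl <- groups[[g]]$label
    n_resp <- sum(lbl != "none")
    if (n_resp == 0L) return(NULL)
    data.frame(group = g, category = cats,
               fraction = as.numeric(table(factor(lbl, levels = cats))[cats]) / n_resp,
               n_responding = n_resp, stringsAsFactors = FALSE)
  })
  dropped <- names(groups)[vapply(out, is.null, TRUE)]
  if (length(dropped))
    message("category_fractions: no responding entries in group(s): ",
            paste(dropped, collapse = ", "))
  fractions <- do.call(rbind, out)
  if (is.null(fractions)) stop("no group has responding entries")
  summary <- do.call(rbind, lapply(cats, function(cc) {
    f <- fractions$fraction[fractions$category == cc]
    data.frame(category = cc, median = stats::median(f),
               q1 = unname(stats::quantile(f, 0.25)),
               q3 = unname(stats::quantile(f, 0.75)))
  }))
  list(fractions = fractions, summary = summary)
}
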