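#' Configuration for the synthetic population generator
#'
#' Builds (and validates) the parameter set for [generate_traceset()] and
#' [generate_stack()].  Defaults emulate a typical glomerular/soma
#' recording session: 5 Hz acquisition for 35 s (175 frames), a 10-s
#' odor pulse starting at frame 25, four odorants plus a mineral-oil
#' solvent control, and two trials per stimulus.
#'
#' Each unit x odorant pair carries two ground-truth pattern weights: an
#' odor weight (its amplitude in the early odor-response window) and a
#' post-odor weight (its amplitude in the window 5 s after offset).  On
#' the latent Gaussian scale the post-odor weights are constructed as
#' `rho_z * z_odor + sqrt(1 - rho_z^2) * z_indep`, with `rho_z` chosen so
#' that the lognormal-scale Pearson correlation equals
#' `post_pattern_corr`; the knob therefore directly sets the expected
#' correlation between a population's odor pattern and its post-odor
#' pattern.
#'
#' @param n_animals number of animals; units are partitioned evenly.
#' @param units_per_animal units recorded per animal.
#' @param odorants stimulus labels; `solvent` must be among them.
#' @param solvent label of the solvent control (near-zero amplitudes).
#' @param trials_per_odor repetitions of each stimulus.
#' @param frame_rate acquisition rate, Hz.
#' @param n_frames recording length in frames.
#' @param stim_onset_frame 0-based frame of odor onset.
#' @param stim_duration odor pulse length, seconds.
#' @param category_mix named probabilities over `on`, `off`, `prolonged`,
#'   `none`; must sum to 1.  Drawn independently per unit x odorant.
#' @param rise_tau GCaMP-like fluorescence rise time constant, seconds.
#' @param decay_tau decay time constant of transient (*on*) responses
#'   after odor offset, seconds.
#' @param post_pattern_corr target odor/post-odor pattern correlation rho
#'   in `[-1, 1]`.
#' @param response_amp_mean,response_amp_sd mean and SD of the lognormal
#'   pattern-weight distribution, in delta-F/F units (the default CV of 1
#'   reflects the strong amplitude heterogeneity of calcium response
#'   populations).
#' @param noise_sd additive Gaussian noise SD, expressed in delta-F/F
#'   units (applied to raw counts as `noise_sd * baseline_f0`).
#' @param bleach_a,bleach_b,bleach_c multiplicative photobleaching
#'   `a * exp(b * frame) + c`; `b` is per frame and should be <= 0.
#' @param baseline_f0 baseline fluorescence, raw counts.
#' @param seed master seed; all stage substreams derive from it.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_animals = 6,
                         units_per_animal = 35,
                         odorants = c("ButL", "ProL", "AceA", "ProA", "MO"),
                         solvent = "MO",
                         trials_per_odor = 2,
                         frame_rate = 5,
                         n_frames = 175,
                         stim_onset_frame = 25,
                         stim_duration = 10,
                         category_mix = c(on = 0.55, off = 0.10,
                                          prolonged = 0.25, none = 0.10),
                         rise_tau = 0.5,
                         decay_tau = 1.2,
                         post_pattern_corr = 0,
                         response_amp_mean = 1.0,
                         response_amp_sd = 1.0,
                         noise_sd = 0.02,
                         bleach_a = 0.1,
                         bleach_b = -0.004,
                         bleach_c = 0.9,
                         baseline_f0 = 1000,
                         seed = 1L) {
  cfg <- list(n_animals = as.integer(n_animals),
              units_per_animal = as.integer(units_per_animal),
              odorants = odorants, solvent = solvent,
              trials_per_odor = as.integer(trials_per_odor),
              frame_rate = frame_rate, n_frames = as.integer(n_frames),
              stim_onset_frame = as.integer(stim_onset_frame),
              stim_duration = stim_duration,
              category_mix = category_mix,
              rise_tau = rise_tau, decay_tau = decay_tau,
              post_pattern_corr = post_pattern_corr,
              response_amp_mean = response_amp_mean,
              response_amp_sd = response_amp_sd,
              noise_sd = noise_sd,
              bleach_a = bleach_a, bleach_b = bleach_b, bleach_c = bleach_c,
              baseline_f0 = baseline_f0, seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  fail <- function(what) stop("invalid synth_config: ", what, call. = FALSE)
  if (cfg$n_animals < 1L) fail("n_animals must be >= 1")
  if (cfg$units_per_animal < 1L) fail("units_per_animal must be >= 1")
  if (cfg$trials_per_odor < 1L) fail("trials_per_odor must be >= 1")
  if (cfg$frame_rate <= 0) fail("frame_rate must be > 0")
  if (!cfg$solvent %in% cfg$odorants) fail("solvent must be listed in odorants")
  mix <- cfg$category_mix
  if (is.null(names(mix)) ||
      !setequal(names(mix), c("on", "off", "prolonged", "none")))
    fail("category_mix must be named over on/off/prolonged/none")
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    fail("category_mix must be non-negative and sum to 1")
  if (abs(cfg$post_pattern_corr) > 1)
    fail("post_pattern_corr must be in [-1, 1]")
  stim_frames <- round(cfg$stim_duration * cfg$frame_rate)
  if (cfg$stim_onset_frame < 0 ||
      cfg$stim_onset_frame + stim_frames > cfg$n_frames)
    fail("stimulus window does not fit inside the recording")
  if (cfg$rise_tau <= 0 || cfg$decay_tau <= 0)
    fail("rise_tau and decay_tau must be > 0")
  if (cfg$noise_sd < 0) fail("noise_sd must be >= 0")
  if (cfg$baseline_f0 <= 0) fail("baseline_f0 must be > 0")
  invisible(cfg)
}

#' Compartment archetype presets
#'
#' Returns a [synth_config()] whose category mixture and odor/post-odor
#' pattern correlation express a recorded compartment's archetype:
#' antennal-lobe signals (`orn_like`, `pn_dendrite_like`, `pn_soma_like`)
#' have post-odor patterns uncorrelated with the odor pattern; Kenyon-cell
#' somata (`kc_soma_like`) combine a high pattern correlation with an
#' elevated fraction of prolonged responses, with `kc_dendrite_like`
#' intermediate.
#'
#' @param name one of `"orn_like"`, `"pn_dendrite_like"`,
#'   `"pn_soma_like"`, `"kc_dendrite_like"`, `"kc_soma_like"`.
#' @param ... overrides passed on to [synth_config()].
#' @return a `synth_config`.
#' @export
synth_preset <- function(name, ...) {
  presets <- list(
    orn_like = list(
      category_mix = c(on = 0.25, off = 0.44, prolonged = 0.27, none = 0.04),
      post_pattern_corr = 0),
    pn_dendrite_like = list(
      category_mix = c(on = 0.75, off = 0.10, prolonged = 0.10, none = 0.05),
      post_pattern_corr = 0),
    pn_soma_like = list(
      category_mix = c(on = 0.70, off = 0.05, prolonged = 0.20, none = 0.05),
      post_pattern_corr = 0),
    kc_dendrite_like = list(
      category_mix = c(on = 0.70, off = 0.01, prolonged = 0.24, none = 0.05),
      post_pattern_corr = 0.25),
    kc_soma_like = list(
      category_mix = c(on = 0.55, off = 0.04, prolonged = 0.36, none = 0.05),
      post_pattern_corr = 0.75))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; valid names: ",
         paste(names(presets), collapse = ", "))
  do.call(synth_config, utils::modifyList(presets[[name]], list(...)))
}

# Deterministic substream seeds derived from the master seed (kept < 2^31).
substream_seed <- function(seed, stage) {
  offs <- c(weights = 101L, categories = 211L, noise = 307L, stack = 401L)
  (as.integer(seed) %% 2000000000L) + offs[[stage]]
}

# --- temporal kernels ------------------------------------------------------
#
# All kernels are functions of time relative to stimulus onset (seconds)
# and are normalised so that the odor-channel kernel averages 1 over the
# odor-pattern window (t = 1..2 s) and the post-channel kernels average 1
# over the post-odor window (t = dur+5..dur+6 s).  A unit's clean trace is
#   odor_weight * S(t) + post_weight * P(t)
# with S the transient stimulus kernel and P a category-specific post
# kernel (delayed bump for on/off units, offset-bridging ramp for
# prolonged units).

kernel_stim <- function(t, dur, rise_tau, decay_tau) {
  k <- ifelse(t <= 0, 0,
       ifelse(t <= dur, 1 - exp(-t / rise_tau),
              (1 - exp(-dur / rise_tau)) * exp(-(t - dur) / decay_tau)))
  k
}

kernel_post_delayed <- function(t, dur, gap = 4, rise = 1.2, decay = 30) {
  d <- t - dur - gap
  ifelse(d <= 0, 0, (1 - exp(-d / rise)) * exp(-d / decay))
}

kernel_post_bridge <- function(t, dur, rise = 1, decay = 40) {
  d <- t - dur
  ifelse(d <= 0, 0, (1 - exp(-d / rise)) * exp(-d / decay))
}

# kernel matrix (frames x 3: S, P_delayed, P_bridge), normalised per window
synth_kernels <- function(cfg) {
  t <- (seq_len(cfg$n_frames) - 1 - cfg$stim_onset_frame) / cfg$frame_rate
  dur <- cfg$stim_duration
  S  <- kernel_stim(t, dur, cfg$rise_tau, cfg$decay_tau)
  Pd <- kernel_post_delayed(t, dur)
  Pb <- kernel_post_bridge(t, dur)
  odor_win <- t >= 1 & t < 2
  post_win <- t >= dur + 5 & t < dur + 6
  if (!any(odor_win) || !any(post_win))
    stop("recording too short for the odor/post-odor pattern windows")
  S  <- S / mean(S[odor_win])
  Pd <- Pd / mean(Pd[post_win])
  Pb <- Pb / mean(Pb[post_win])
  cbind(stim = S, post_delayed = Pd, post_bridge = Pb)
}

# Minimum post/odor weight ratio that keeps a prolonged trace above the
# 1/e-of-max criterion throughout the 5 s after offset; the binding case
# is 5 s after offset, where the stimulus kernel has decayed to ~4% of
# its maximum and the bridge kernel must make up the difference (~0.34
# at the default kernel taus; 0.45 leaves noise margin).
PROLONGED_MIN_RATIO <- 0.45

#' Generate a synthetic multi-trial population recording
#'
#' Simulates raw fluorescence for every unit x frame x trial following the
#' configured design: category-specific clean delta-F/F kernels scaled by
#' ground-truth pattern weights, multiplied by baseline fluorescence and a
#' multiplicative exponential bleach, plus additive Gaussian noise.
#' Identical seeds give bit-identical output.
#'
#' @param cfg a [synth_config()].
#' @return list with elements `traceset` (raw fluorescence [traceset]) and
#'   `ground_truth` (data.frame: one row per unit x odorant with the true
#'   category and the odor/post-odor pattern weights, plus the bleach
#'   parameters as attributes).
#' @export
generate_traceset <- function(cfg) {
  validate_synth_config(cfg)
  n_units_total <- cfg$n_animals * cfg$units_per_animal
  animals <- sprintf("animal%02d", rep(seq_len(cfg$n_animals),
                                       each = cfg$units_per_animal))
  unit_ids <- sprintf("%s_u%03d", animals,
                      rep(seq_len(cfg$units_per_animal), cfg$n_animals))
  units <- data.frame(unit = unit_ids, animal = animals,
                      stringsAsFactors = FALSE)
  resp_odors <- setdiff(cfg$odorants, cfg$solvent)
  n_resp <- length(resp_odors)

  # --- ground-truth pattern weights (substream: weights) -------------------
  # Amplitudes are lognormal (positive, right-skewed, CV ~ 1 by default,
  # matching the amplitude heterogeneity of calcium response populations).
  # The target Pearson correlation rho between the odor and post-odor
  # weights is imposed through a Gaussian copula whose latent correlation
  # rho_z is the exact inversion of the lognormal moment formula, so that
  # cor(u, v) = rho in expectation on the observed (lognormal) scale.
  rho <- cfg$post_pattern_corr
  s2 <- log(1 + (cfg$response_amp_sd / cfg$response_amp_mean)^2)
  meanlog <- log(cfg$response_amp_mean) - s2 / 2
  rho_z_arg <- 1 + rho * (exp(s2) - 1)
  if (rho_z_arg <= 0) {
    warning("post_pattern_corr below the attainable lognormal minimum; ",
            "saturating at the countermonotonic bound", call. = FALSE)
    rho_z_arg <- exp(-s2)
  }
  rho_z <- max(-1, min(1, log(rho_z_arg) / s2))
  set.seed(substream_seed(cfg$seed, "weights"))
  z_u <- matrix(stats::rnorm(n_units_total * n_resp), n_units_total)
  z_w <- matrix(stats::rnorm(n_units_total * n_resp), n_units_total)
  z_v <- rho_z * z_u + sqrt(1 - rho_z^2) * z_w
  u <- exp(meanlog + sqrt(s2) * z_u)
  v <- exp(meanlog + sqrt(s2) * z_v)

  # --- categories (substream: categories) ----------------------------------
  set.seed(substream_seed(cfg$seed, "categories"))
  cats <- matrix(sample(names(cfg$category_mix), n_units_total * n_resp,
                        replace = TRUE, prob = cfg$category_mix),
                 n_units_total)
  # prolonged traces need post_weight >= PROLONGED_MIN_RATIO * odor_weight
  # to stay above 1/e of their maximum; enforced by swapping (u, v) where
  # violated, which preserves both marginals and the pair correlation
  # because the copula is exchangeable
  swap <- cats == "prolonged" & v < PROLONGED_MIN_RATIO * u
  tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
  u[cats == "off"] <- 0
  u[cats == "none"] <- 0
  v[cats == "none"] <- 0

  gt <- data.frame(
    animal = rep(units$animal, n_resp),
    unit = rep(units$unit, n_resp),
    odor = rep(resp_odors, each = n_units_total),
    category = as.vector(cats),
    odor_weight = as.vector(u),
    post_weight = as.vector(v),
    stringsAsFactors = FALSE)
  if (cfg$solvent %in% cfg$odorants) {
    gt <- rbind(gt, data.frame(
      animal = units$animal, unit = units$unit, odor = cfg$solvent,
      category = "none", odor_weight = 0, post_weight = 0,
      stringsAsFactors = FALSE))
  }

  # --- clean kernels -> raw fluorescence -----------------------------------
  K <- synth_kernels(cfg)
  nf <- cfg$n_frames
  clean <- array(0, dim = c(n_units_total, nf, length(cfg$odorants)),
                 dimnames = list(NULL, NULL, cfg$odorants))
  for (j in seq_len(n_resp)) {
    bridge <- cats[, j] == "prolonged"
    clean[, , resp_odors[j]] <-
      outer(u[, j], K[, "stim"]) +
      outer(v[, j] * !bridge, K[, "post_delayed"]) +
      outer(v[, j] * bridge, K[, "post_bridge"])
  }

  trials <- data.frame(
    odor = rep(cfg$odorants, each = cfg$trials_per_odor),
    rep = rep(seq_len(cfg$trials_per_odor), length(cfg$odorants)),
    stringsAsFactors = FALSE)
  bleach <- cfg$bleach_a * exp(cfg$bleach_b * (seq_len(nf) - 1)) + cfg$bleach_c

  set.seed(substream_seed(cfg$seed, "noise"))
  data <- array(NA_real_, dim = c(n_units_total, nf, nrow(trials)))
  for (k in seq_len(nrow(trials))) {
    noise <- matrix(stats::rnorm(n_units_total * nf,
                                 sd = cfg$noise_sd * cfg$baseline_f0),
                    n_units_total, nf)
    data[, , k] <- cfg$baseline_f0 *
      (1 + clean[, , trials$odor[k]]) *
      matrix(bleach, n_units_total, nf, byrow = TRUE) + noise
  }

  ts <- traceset(data, units, trials, cfg$frame_rate, cfg$stim_onset_frame,
                 cfg$stim_duration, signal_kind = "raw")
  # traceset() reorders units canonically; ground truth is already in the
  # same (animal, unit) order because unit ids embed the animal
  attr(gt, "bleach") <- c(a = cfg$bleach_a, b = cfg$bleach_b,
                          c = cfg$bleach_c)
  attr(gt, "seed") <- cfg$seed
  list(traceset = ts, ground_truth = gt)
}

#' Regular grid layout of square unit footprints
#'
#' Places `n` non-overlapping `size` x `size` footprints on a regular grid
#' inside a `frame_h` x `frame_w` frame, for use with [generate_stack()].
#'
#' @param n number of footprints.
#' @param size footprint side length, pixels.
#' @param frame_h,frame_w frame dimensions, pixels.
#' @param gap spacing between footprints, pixels.
#' @return data.frame with columns `label`, `row`, `col` (0-based footprint
#'   centers) and `size`.
#' @export
grid_layout <- function(n, size = 7, frame_h = 120, frame_w = 160, gap = 2) {
  step <- size + gap
  half <- (size - 1L) %/% 2L
  rows <- seq(half + 1L, frame_h - size %/% 2L - 1L, by = step)
  cols <- seq(half + 1L, frame_w - size %/% 2L - 1L, by = step)
  if (length(rows) * length(cols) < n)
    stop("frame too small for ", n, " footprints of size ", size)
  pos <- expand.grid(row = rows, col = cols)[seq_len(n), , drop = FALSE]
  data.frame(label = sprintf("unit%03d", seq_len(n)),
             row = pos$row, col = pos$col, size = rep(size, length.out = n),
             stringsAsFactors = FALSE)
}

#' Render a synthetic recording as an image stack
#'
#' Renders the units of one trial of [generate_traceset()] output into
#' spatial footprints on a noisy background, so that the ROI operations
#' ([extract_box_trace()], [bin_stack()]) can be validated against ground
#' truth: the mean over a unit's footprint recovers the unit's raw trace
#' up to pixel noise.
#'
#' @param cfg a [synth_config()]; `n_animals * units_per_animal` should be
#'   at least `nrow(layout)`; the first `nrow(layout)` units are rendered.
#' @param layout data.frame with columns `label`, `row`, `col`, `size`
#'   (0-based footprint centers), e.g. from [grid_layout()]; footprints
#'   must be non-overlapping and inside the frame.
#' @param odor,rep which trial of the simulated session to render.
#' @param frame_h,frame_w frame dimensions in pixels.
#' @param pixel_noise_sd per-pixel additive noise SD, raw counts.
#' @return list with elements `stack` (an [image_stack]), `ground_truth`
#'   (as in [generate_traceset()], subset to the rendered units) and
#'   `layout`.
#' @export
generate_stack <- function(cfg, layout, odor = NULL, rep = 1,
                           frame_h = 120, frame_w = 160,
                           pixel_noise_sd = 0) {
  sim <- generate_traceset(cfg)
  ts <- sim$traceset
  if (is.null(odor)) odor <- setdiff(cfg$odorants, cfg$solvent)[1L]
  tr <- which(ts$trials$odor == odor & ts$trials$rep == rep)
  if (length(tr) != 1L) stop("no such trial: ", odor, " rep ", rep)
  if (nrow(layout) > n_units(ts))
    stop("layout has more footprints than generated units")

  # footprint pixel sets; reject overlap / out-of-bounds
  occupied <- matrix(FALSE, frame_h, frame_w)
  foot <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    s <- layout$size[i]
    r0 <- layout$row[i] - (s - 1L) %/% 2L
    c0 <- layout$col[i] - (s - 1L) %/% 2L
    if (r0 < 0L || c0 < 0L || r0 + s > frame_h || c0 + s > frame_w)
      stop("footprint '", layout$label[i], "' exceeds the frame")
    px <- as.matrix(expand.grid(row = r0:(r0 + s - 1L),
                                col = c0:(c0 + s - 1L))) + 1L
    if (any(occupied[px])) stop("overlapping footprints in layout")
    occupied[px] <- TRUE
    foot[[i]] <- px
  }

  nf <- n_frames(ts)
  bleach <- cfg$bleach_a * exp(cfg$bleach_b * (seq_len(nf) - 1)) + cfg$bleach_c
  set.seed(substream_seed(cfg$seed, "stack"))
  data <- array(stats::rnorm(nf * frame_h * frame_w, sd = pixel_noise_sd),
                dim = c(nf, frame_h, frame_w))
  data <- data + rep(cfg$baseline_f0 * bleach, frame_h * frame_w)
  for (i in seq_len(nrow(layout))) {
    trace <- ts$data[i, , tr]
    px <- foot[[i]]
    npx <- nrow(px)
    idx <- cbind(rep(seq_len(nf), each = npx),
                 rep(px[, 1L], nf), rep(px[, 2L], nf))
    vals <- rep(trace, each = npx)
    if (pixel_noise_sd > 0)
      vals <- vals + stats::rnorm(length(vals), sd = pixel_noise_sd)
    data[idx] <- vals
  }
  stack <- image_stack(data, cfg$frame_rate, cfg$stim_onset_frame,
                       stim_duration = cfg$stim_duration,
                       odor = odor, rep = rep,
                       animal = ts$units$animal[1L])
  gt <- sim$ground_truth
  gt <- gt[gt$unit %in% ts$units$unit[seq_len(nrow(layout))] &
             gt$odor == odor, , drop = FALSE]
  list(stack = stack, ground_truth = gt, layout = layout)
}

#' Write ground truth / configs to disk
#'
#' @param gt ground-truth data.frame from [generate_traceset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  data.table::fwrite(gt, path)
  invisible(path)
}

#' Serialize a synth_config to YAML (and back)
#' @param cfg a [synth_config()].
#' @param path YAML file path.
#' @return `read_synth_config()` returns a validated `synth_config`.
#' @export
write_synth_config <- function(cfg, path) {
  raw <- unclass(cfg)
  raw$category_mix <- as.list(raw$category_mix)  # keep names in YAML
  yaml::write_yaml(raw, path, precision = 15L)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$category_mix <- unlist(raw$category_mix)
  do.call(synth_config, raw)
}
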