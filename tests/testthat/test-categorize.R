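# hand-built single traces on the default geometry: 175 frames at 5 Hz,
# onset frame 25, offset frame 75 (10-s stimulus), categorizer windows
# relative to those
kernel_trace <- function(stim_value = 0, dip_value = 0, post_value = 0,
                         pre_noise = NULL) {
  tr <- numeric(175)
  tr[11:25] <- if (is.null(pre_noise)) 0 else pre_noise
  tr[27:75] <- stim_value          # during stimulus
  tr[77:100] <- dip_value          # offset .. offset + 5 s
  tr[99:103] <- post_value         # off evaluation window (centred frame 100)
  tr
}

test_that("response threshold is 2.57 x sample SD of the pre-window", {
  cfg <- categorize_config()
  tr <- numeric(175)
  set.seed(7)
  tr[11:25] <- stats::rnorm(15, sd = 0.02)
  expect_equal(response_threshold(tr, cfg),
               2.57 * stats::sd(tr[11:25]), tolerance = 1e-14)
  # printed example: SD 0.02 -> threshold 0.0514
  tr2 <- numeric(175)
  tr2[11:25] <- c(rep(-0.02, 7), rep(0.02, 7), 0) *
    0.02 / stats::sd(c(rep(-0.02, 7), rep(0.02, 7), 0))
  expect_equal(response_threshold(tr2, cfg), 2.57 * 0.02, tolerance = 1e-12)
})

test_that("zero pre-stimulus variance yields threshold 0 with a warning", {
  tr <- numeric(175)
  expect_warning(thr <- response_threshold(tr), "zero pre-stimulus")
  expect_equal(thr, 0)
})

test_that("the decision tree forces on / prolonged / off / none", {
  cfg <- categorize_config()
  sw <- c(25L, 75L)
  noise <- stats::rnorm(15, sd = 0.01)

  # decays to 0.30 of max within 5 s of offset -> on (0.30 < 1/e)
  on_tr <- kernel_trace(stim_value = 1, dip_value = 0.30, post_value = 0.30,
                        pre_noise = noise)
  expect_equal(categorize_response(on_tr, sw, cfg, 5)$label, "on")

  # sustained at 0.50 of max through offset + 5 s -> prolonged
  pro_tr <- kernel_trace(stim_value = 1, dip_value = 0.50, post_value = 0.50,
                         pre_noise = noise)
  expect_equal(categorize_response(pro_tr, sw, cfg, 5)$label, "prolonged")

  # flat during stimulus, rising only after offset -> off
  off_tr <- kernel_trace(stim_value = 0, dip_value = 0, post_value = 0.8,
                         pre_noise = noise)
  expect_equal(categorize_response(off_tr, sw, cfg, 5)$label, "off")

  # nothing anywhere -> none
  none_tr <- kernel_trace(pre_noise = noise)
  expect_equal(categorize_response(none_tr, sw, cfg, 5)$label, "none")

  # purely negative deflection -> none (one-sided threshold)
  neg_tr <- kernel_trace(stim_value = -1, pre_noise = noise)
  expect_equal(categorize_response(neg_tr, sw, cfg, 5)$label, "none")
})

test_that("the boundary of the 1/e rule falls on the correct side", {
  cfg <- categorize_config()
  sw <- c(25L, 75L)
  noise <- stats::rnorm(15, sd = 1e-4)
  just_below <- kernel_trace(1, dip_value = exp(-1) - 0.01,
                             post_value = exp(-1) - 0.01, pre_noise = noise)
  just_above <- kernel_trace(1, dip_value = exp(-1) + 0.01,
                             post_value = exp(-1) + 0.01, pre_noise = noise)
  expect_equal(categorize_response(just_below, sw, cfg, 5)$label, "on")
  expect_equal(categorize_response(just_above, sw, cfg, 5)$label, "prolonged")
})

test_that("NaN frames inside decision windows flag the entry as none", {
  cfg <- categorize_config()
  tr <- kernel_trace(1, 0.5, 0.5, pre_noise = stats::rnorm(15, sd = 0.01))
  tr[50] <- NaN
  res <- categorize_response(tr, c(25L, 75L), cfg, 5)
  expect_equal(res$label, "none")
  expect_true(res$flagged)
})

test_that("labels are scale invariant and monotone in the threshold", {
  set.seed(8)
  sw <- c(25L, 75L)
  for (i in 1:25) {
    tr <- stats::rnorm(175, sd = 0.05)
    tr[26:75] <- tr[26:75] + stats::runif(1, 0, 1.5) *
      (1 - exp(-(1:50) / 3))
    lab1 <- categorize_response(tr, sw, categorize_config(), 5)$label
    # positive rescaling leaves the label unchanged
    lab_scaled <- categorize_response(tr * 12.5, sw, categorize_config(), 5)$label
    expect_equal(lab_scaled, lab1)
    # raising the multiplier never converts none into a responding label
    lab_low <- categorize_response(tr, sw,
                                   categorize_config(threshold_multiplier = 1.5),
                                   5)$label
    lab_high <- categorize_response(tr, sw,
                                    categorize_config(threshold_multiplier = 4),
                                    5)$label
    if (lab_low == "none") expect_equal(lab_high, "none")
  }
})

test_that("category fractions count responders and groups correctly", {
  tab <- data.frame(
    animal = c("a1", "a1", "a1", "a1", "a2"),
    unit = sprintf("u%d", 1:5), odor = "A",
    label = c("on", "on", "off", "prolonged", "none"))
  fr <- suppressMessages(category_fractions(tab, group_by = "animal"))
  a1 <- fr$fractions[fr$fractions$group == "a1", ]
  expect_equal(a1$fraction[a1$category == "on"], 0.5)
  expect_equal(a1$fraction[a1$category == "off"], 0.25)
  expect_equal(a1$fraction[a1$category == "prolonged"], 0.25)
  expect_equal(sum(a1$fraction), 1)
  # group with no responders is excluded with a message
  expect_message(category_fractions(tab, group_by = "animal"), "a2")
  # all-on degenerate group
  all_on <- data.frame(animal = "a1", unit = c("u1", "u2"), odor = "A",
                       label = "on")
  fr2 <- category_fractions(all_on)
  expect_equal(fr2$summary$median, c(1, 0, 0))
})

test_that("generated category mixture is recovered from the labels", {
  mix <- c(on = 0.25, off = 0.44, prolonged = 0.27, none = 0.04)
  cfg <- synth_config(n_animals = 5, units_per_animal = 60,
                      category_mix = mix, noise_sd = 0.01, seed = 21)
  ts <- compute_dff(generate_traceset(cfg)$traceset)
  res <- suppressMessages(categorize_traceset(ts))
  fr <- suppressMessages(category_fractions(res, group_by = "animal"))
  target <- mix[c("on", "off", "prolonged")] / sum(mix[c("on", "off", "prolonged")])
  expect_lt(max(abs(fr$summary$median - unname(target))), 0.05)
})

test_that("per-unit aggregation majorities and tie-breaks are honored", {
  # build a 1-unit, 3-trial traceset: two off responses, one none
  data <- array(0, dim = c(1, 175, 3))
  set.seed(10)
  for (k in 1:3) data[1, 11:25, k] <- stats::rnorm(15, sd = 0.005)
  data[1, 99:103, 1:2] <- 1
  ts <- traceset(data, units = data.frame(unit = "u1", animal = "a1"),
                 trials = data.frame(odor = "A", rep = 1:3),
                 frame_rate = 5, stim_onset_frame = 25, stim_duration = 10,
                 signal_kind = "dff")
  res <- suppressMessages(categorize_traceset(ts))
  expect_equal(res$per_unit$label, "off")
  expect_equal(sort(res$per_trial$label), c("none", "off", "off"))
  # tie between on and off resolves toward the weaker claim (on)
  data2 <- array(0, dim = c(1, 175, 2))
  for (k in 1:2) data2[1, 11:25, k] <- stats::rnorm(15, sd = 0.005)
  data2[1, 30:60, 1] <- 1       # on response in trial 1 only
  data2[1, 99:103, 2] <- 1      # off response in trial 2 only
  ts2 <- traceset(data2, units = data.frame(unit = "u1", animal = "a1"),
                  trials = data.frame(odor = "A", rep = 1:2),
                  frame_rate = 5, stim_onset_frame = 25, stim_duration = 10,
                  signal_kind = "dff")
  res2 <- suppressMessages(categorize_traceset(ts2))
  expect_equal(res2$per_unit$label, "on")
})

test_that("labels agree with ground truth at the default noise level", {
  cfg <- synth_config(n_animals = 3, units_per_animal = 40, seed = 7)
  sim <- generate_traceset(cfg)
  ts <- compute_dff(sim$traceset)
  res <- suppressMessages(categorize_traceset(ts))
  truth <- gt_labels_for(sim$ground_truth, res$per_unit)
  expect_gte(mean(res$per_unit$label == truth), 0.95)
})
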