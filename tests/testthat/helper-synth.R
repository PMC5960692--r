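# shared fixtures: small synthetic configurations used across test files

config_with <- function(defaults, overrides) {
  do.call(synth_config, utils::modifyList(defaults, overrides))
}

# clean (noise- and bleach-free) config: extracted dF/F equals the kernels
clean_config <- function(...) {
  config_with(list(n_animals = 2, units_per_animal = 20, noise_sd = 0,
                   bleach_a = 0, bleach_c = 1, seed = 101), list(...))
}

small_config <- function(...) {
  config_with(list(n_animals = 2, units_per_animal = 15, seed = 101),
              list(...))
}

# tiny recording geometry for fast decode/permutation tests
tiny_config <- function(...) {
  config_with(list(n_animals = 2, units_per_animal = 10, n_frames = 80,
                   stim_onset_frame = 25, stim_duration = 4,
                   odorants = c("A", "B", "MO"), solvent = "MO",
                   noise_sd = 0.05, seed = 101), list(...))
}

# ground-truth label lookup aligned to a per-unit category table
gt_labels_for <- function(gt, per_unit) {
  gt$category[match(paste(per_unit$unit, per_unit$odor),
                    paste(gt$unit, gt$odor))]
}

# deterministic small image stack with known pixel values
ramp_stack <- function(nf = 6, h = 12, w = 16, frame_rate = 5, onset = 2) {
  data <- array(0, dim = c(nf, h, w))
  for (f in seq_len(nf))
    data[f, , ] <- outer(seq_len(h), seq_len(w), function(r, c) r + c / 100) + f
  image_stack(data, frame_rate, onset, stim_duration = 0.4)
}
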