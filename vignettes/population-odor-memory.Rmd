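---
title: "Analysing odor and post-odor population calcium dynamics with odortrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing odor and post-odor population calcium dynamics with odortrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odortrace)
```

## The scientific question

When an animal associates an odor with a reinforcer that arrives only
after the odor has ended (trace conditioning), the nervous system must
retain some representation of the odor across the gap. A candidate
substrate is stimulus-outlasting calcium activity: if the *post-odor*
population pattern still resembles (or predicts) the *odor* pattern, a
downstream coincidence detector can associate the past odor with the
present reinforcer.

`odortrace` implements the analysis chain used to test this idea on
multi-trial calcium-imaging recordings of neural populations:

1. **Preprocessing** — ΔF/F conversion and exponential photobleaching
   correction (`compute_dff()`, `fit_bleach()`, `subtract_bleach()`).
2. **ROI extraction** — box averages over glomerulus/soma centers and
   spatial binning of dendritic neuropil (`extract_box_trace()`,
   `bin_stack()`), plus an activity filter (`filter_active_units()`).
3. **Response-dynamics categorization** — *on* / *off* / *prolonged* /
   *none* per unit × odorant (`categorize_traceset()`).
4. **Time-resolved pattern correlation** — Pearson correlation between
   population vectors at all pairs of time points, with significance
   masking and an animal-level bootstrap (`corr_matrix()`,
   `corr_trace()`, `bootstrap_corr()`, `pairwise_window_corr()`).
5. **Decoding** — sliding-window ν-SVM classification of odorant
   identity with a label-permutation chance band (`sliding_decode()`,
   `permutation_chance()`).

Because the recordings such analyses target are generally not publicly
deposited, the package ships a ground-truth synthetic generator
(`generate_traceset()`, `generate_stack()`, `synth_preset()`) that
emulates the relevant population statistics, so every stage is testable
end to end.

## Conventions

All frame indices are **0-based** and all windows **half-open** `[a, b)`.
Time `t = 0` s is stimulus onset. The default acquisition emulates 5 Hz
for 35 s (175 frames) with a 10-s odor pulse starting at frame 25, four
odorants (ButL, ProL, AceA, ProA) plus a mineral-oil solvent control
(MO), and two trials per stimulus.

Two named pattern windows recur throughout: the **odor response
pattern** is the per-unit mean ΔF/F over `t = 1–2` s (5 frames), and the
**post-odor response pattern** the mean over `t = 15–16` s — 5 s after
offset of a 10-s stimulus, a delay at which behavioural evidence shows
an odor trace is still usable.

## Preprocessing model

ΔF/F is `(F_i − F_B)/F_B` with `F_B` the mean raw fluorescence over the
background window, frames `[10, 25)` — the 15 frames preceding the
default stimulus onset. Reading the window as half-open is the only
interpretation consistent with a 15-frame count.

Bleaching is modelled as `F(t) = a·e^{bt} + c` (t in frames, `b ≤ 0`
expected) and subtracted per unit × trial after ΔF/F conversion. The
default fit window excludes the response period (stimulus onset through
5 s after offset), because a large odor response inside the fit window
biases `b`; a full-trace mode (`bleach_fit_window(ts, full = TRUE)`)
reproduces the literal fit-over-everything reading. **Known
limitation:** when post-odor or prolonged responses persist beyond 5 s
after offset — which the synthetic generator produces deliberately, and
real mushroom-body somata show — even the exclusion window is
contaminated and the subtraction distorts response traces. For such
data, fit bleaching on blank (solvent) trials or restrict the correction
to compartments with transient responses; the package's own validation
of the categorizer therefore runs on uncorrected ΔF/F, and bleach-fit
recovery is validated on solvent trials.

Fitting uses deterministic initialization (amplitude from first-vs-last
values, rate from the log-ratio of the first and last thirds), tries the
mirrored (rising) start as well, and falls back to a linear model with
`b` pinned at −10⁻⁴/frame when neither converges (flagged). A positive
fitted `b` warns (possible focus drift) but is not an error.

## Categorization rules

A response crosses threshold when it exceeds `2.57 × SD` of the
pre-stimulus signal — 2.57 SD corresponds to a one-sided normal
significance of p < 0.005. The decision tree per trace:

* crossing during the stimulus window, and falling below **1/e (37%)**
  of the stimulus-window maximum at some frame within 5 s after offset →
  **on**; crossing but never falling below → **prolonged**;
* no stimulus-window crossing, but the 1-s window centred 5 s after
  offset exceeds threshold (window mean) → **off**;
* otherwise **none**. Purely negative (inhibitory) deflections are
  *none*: the thresholds are one-sided positive.

Two readings of the categorization rules are genuinely open and are
configurable: the 1/e decline can be checked at *any frame* within the
5-s window (default) or only at the endpoint (`decline_rule`), and the
off criterion can use the window mean (default) or any crossing in the
5 s after offset (`off_rule`).

One default deviates from the most literal reading: a stimulus-window
"crossing" requires **2 consecutive frames** above threshold
(`min_frames = 2`), not 1. With a per-frame false-positive rate of 0.005
and a 50-frame stimulus window, a truly silent trace crosses by chance
with probability ≈ 1 − 0.995⁵⁰ ≈ 22% (more once the SD itself is
estimated from 15 frames), so single-frame crossing structurally
mislabels off and none units at a rate far above the package's own
calibration targets. Two consecutive frames is 400 ms at 5 Hz — shorter
than any GCaMP transient — and restores calibration;
`min_frames = 1` remains available.

Per-trial labels are aggregated per unit × odorant by majority, ties
broken toward the weaker claim (`none < on < off < prolonged`).

## Pattern correlation

Correlation matrices are built from single-frame population vectors
(units pooled across animals in a fixed canonical order); p-values use
the t transform `t = r·sqrt((n−2)/(1−r²))` with `n` = number of pooled
units, masked per cell at α = 0.005 with no multiple-testing correction
(each cell is reported at its own significance, as is conventional for
these displays). Correlation traces average the matrix rows of a 1-s
reference window; variability envelopes come from resampling animals
with replacement (1000 replicates by default) and taking the per-time SD
across replicates — a duplicated animal contributes its units twice.

`pairwise_window_corr()` reduces the same machinery to the two named
pattern windows and reports three trial-by-trial tables (odor vs odor,
post vs post, odor vs post); the diagonal of the odor-vs-post table is
the summary statistic for "does the post-odor pattern resemble the odor
pattern?".

## Decoding

`decode_from()` trains a one-vs-one ν-SVM (ν = 0.9, linear kernel,
per-unit z-scoring fitted on training samples only) on the 2-s-averaged
population pattern at a training time, and classifies single-frame
patterns at every test time. Cross-validation holds out one repetition
of every odorant per fold ("leave one repetition out"): with per-trial
holdout the training folds become class-unbalanced, and ν = 0.9 is then
infeasible for the underlying one-vs-one subproblems (libsvm requires
`ν·(n_i+n_j)/2 ≤ min(n_i, n_j)`). The grouped scheme holds out every
trial exactly once while keeping folds balanced. When label permutation
unbalances a fold anyway, ν is clipped per fold to the largest feasible
value and the result flagged. A resubstitution mode (`cv = "resub"`)
mirrors the regime in which train-equals-test performance trivially
reaches 1.

`sliding_decode()` summarises each training time by the mean success
over the 10-s stimulus window; `permutation_chance()` reruns the
identical pipeline on 250 whole-trial label shuffles and reports the
permutation mean and its 95th percentile — the implementation of the
"upper 95% confidence interval" bound, since no closed formula is
implied by a permutation approach.

One scoring subtlety: with a solvent class whose trials are essentially
silent, the blank stimulus is identifiable at *every* time point, which
adds a constant ≈ 1/k floor to the success curve that has nothing to do
with odor-identity memory. The `score_trials` argument therefore lets an
analysis train on all classes but score success on the odor trials only;
the package's compartment-contrast validations use it, and the default
(score everything) is unchanged.

## The synthetic generator

`generate_traceset()` draws, per unit × odorant, a true category from
`category_mix` and two ground-truth pattern weights: an odor weight `u`
and a post-odor weight `v`. A unit's clean ΔF/F trace is
`u·S(t) + v·P(t)` where `S` is a transient stimulus kernel
(difference-of-exponentials: rise τ = 0.5 s, decay τ = 1.2 s after
offset — GCaMP6f-like) and `P` a category-specific post kernel: a
delayed bump beginning 4 s after offset (on and off units; the delayed
rise leaves the decay dip that defines *on* intact for any `v`) or a
ramp starting at offset that bridges smoothly into the post window
(prolonged units). Kernels are normalised so `u` and `v` are exactly the
expected pattern values in the odor and post-odor windows. Off units
have `u = 0`, none units `u = v = 0`, and the solvent class is silent.
Raw fluorescence is
`baseline_f0 · (1 + ΔF/F_clean) · (a·e^{bt} + c) + ε`,
with multiplicative bleaching (defaults `a = 0.1`, `b = −0.004`/frame,
`c = 0.9`: ≈ 5% loss over 35 s) and additive Gaussian noise
(`noise_sd = 0.02` ΔF/F — a realistic pre-stimulus fluctuation for
averaged ROIs).

Three design choices matter for interpretation:

* **Amplitudes are lognormal with CV = 1** (mean 1 ΔF/F). Response
  amplitudes across units are strongly right-skewed in real data, and
  this choice is also what makes the correlation knob accurate: with
  narrow amplitude distributions, the cluster of non-responding
  (`u = 0`) units dominates the population Pearson r regardless of the
  configured correlation.
* **The correlation knob uses a Gaussian copula with exact moment
  inversion.** `post_pattern_corr = ρ` sets the *observed-scale* Pearson
  correlation between `u` and `v`; the latent normal correlation is
  `ρ_z = log(1 + ρ(e^{s²} − 1))/s²`. Strongly negative targets saturate
  at the countermonotonic lognormal bound (with a warning).
* **The prolonged constraint is enforced by swapping.** A prolonged
  trace stays above 1/e of its maximum only if `v ≥ 0.45·u` at the
  default kernels; where violated, `(u, v)` are swapped rather than
  floored. Because the copula is exchangeable this preserves both
  marginals and the pair correlation exactly, whereas flooring would
  inject spurious odor–post correlation.

Per-animal structure is a plain partition of units: animal identity
affects only bootstrap resampling, not response statistics (no model of
between-animal variance is imposed). A single master seed spawns fixed
substream seeds for weights, categories, noise and stack rendering, so
stages can be regenerated independently and identical seeds give
bit-identical output.

The presets encode compartment archetypes: `orn_like`
(on/off/prolonged ≈ 25/44/27% among responders, ρ = 0),
`pn_dendrite_like` (on-dominated, ρ = 0), `pn_soma_like` (ρ = 0),
`kc_dendrite_like` (ρ = 0.25), `kc_soma_like` (elevated prolonged
fraction, ρ = 0.75).

What the generator does **not** emulate: trial-to-trial amplitude
variability beyond additive noise, negative (inhibitory) responses,
movement artifacts, between-animal response differences, and any
biophysical network structure. Passing tests on this generator therefore
show that the pipeline recovers the statistical structure it was built
to detect — not that real recordings contain that structure.

## Worked example

```{r example, eval = FALSE}
library(odortrace)

# a Kenyon-cell-soma-like population: 6 animals x 35 units
cfg <- synth_preset("kc_soma_like", seed = 5)
sim <- generate_traceset(cfg)
ts  <- compute_dff(sim$traceset)

# odor vs post-odor pattern similarity, per stimulation
pw <- pairwise_window_corr(ts)
mean(diag(pw$odor_vs_post)[!grepl("^MO", colnames(pw$odor_vs_post))])
#> ~0.77 for the configured rho = 0.75

# decoding odor identity from a training window 5 s after offset
sc  <- which(ts$trials$odor != "MO")
res <- sliding_decode(ts, decode_config(), train_frames = 100L,
                      score_trials = sc)
ch  <- permutation_chance(ts, decode_config(), train_frames = 100L,
                          score_trials = sc)
c(success = res$stim_avg, chance95 = ch$chance_upper)
#> ~0.95 vs ~0.48: the post-odor pattern identifies the odor
```

The same analysis under `synth_preset("orn_like")` stays inside the
chance band — the package reproduces, at synthetic scale, the contrast
between early sensory layers (post-odor patterns uninformative about
identity) and Kenyon-cell somata (post-odor patterns carrying a sensory
odor memory).

## Problem sizes and numerical choices

The validation suite and the acceptance script run at what a reviewer
can reproduce on a laptop: populations of 200 units (4–6 animals), 5
stimulus classes × 2 trials, 250 label permutations for chance bands,
and 100 repeats for null-calibration checks. Bleach-rate recovery is
asserted at noise SD 0.002 ΔF/F on solvent trials over the full trace:
an exponential with ≈ 5% total decay over 175 frames is too
ill-conditioned for 10%-accurate rate recovery at much higher noise, and
response-carrying trials bias the fit as discussed above. Zero-variance
patterns yield undefined correlation cells (excluded and counted, never
silently zeroed); zero pre-stimulus variance yields threshold 0 with a
warning, so any positive deflection counts as a crossing; SVM tie-breaks
follow libsvm's deterministic voting order.
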