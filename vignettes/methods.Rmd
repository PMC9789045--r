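---
title: "Models and methods behind enspff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind enspff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enspff)
```

`enspff` reimplements, as a tested pipeline, the quantification stack used to
study uptake of alpha-synuclein preformed fibrils (PFFs) in cultured enteric
neurons: segmentation of immunofluorescence micrographs into morphological
compartments, per-compartment intensity metrics, spike and burst detection
from microelectrode-array (MEA) voltage traces, and a hierarchical
statistical layer. Because the original raw images and recordings are not
bundled, every stage is exercised against ground-truthed synthetic data whose
generators are first-class, tested package code. This vignette explains the
models, the defaults, and the choices made where the original analysis left
the construction open.

## Synthetic scenes: what they emulate and what they do not

`generate_scene()` renders a four-channel 8-bit micrograph with exact ground
truth. Somas are disks (radius 18–28 px by default at 512×512), each with a
concentric nucleus at half the soma radius; neurites are smooth random-walk
polylines of fixed width (5 px) emanating from soma boundaries. Channels are
two-level (foreground/background) images: nuclear stain (DAPI) bright at
nuclei, beta-3 tubulin (B3T) bright over the whole neuron morphology, the
aggregated alpha-synuclein channel bright over the neuron at a
group-dependent level, and the PFF fluorescent tag carrying small bright
puncta placed inside the neuron. Noise is additive Gaussian (default SD 15
uint8 units) with optional Poisson shot noise.

The defaults are free parameters, not calibrated to the original study —
the source acquisitions' intensity and noise magnitudes were never
published. They are chosen to be a realistic, separable-but-noisy 8-bit
immunofluorescence regime: foreground/background contrasts of roughly
170–190 uint8 units against noise SD 15 give a signal-to-noise ratio around
12, typical of well-stained fixed cultures. What the generator deliberately
omits: point-spread-function blur, uneven illumination, photobleaching, and
overlapping cells. Passing segmentation benchmarks on these scenes therefore
demonstrates correctness of the morphology algebra and robustness to pixel
noise, not performance on hard real-world images.

## Morphology segmentation

The compartment decomposition follows the study's mask structure — whole
image, neuron, soma, neurite — with the construction details, unstated in
the original, fixed as follows:

* **Neuron** (`segment_neuron()`): threshold the B3T channel (per-image Otsu
  by default, a fixed uint8 threshold optionally), then disk-element closing
  (radius 2 px, bridges neurite gaps), opening (radius 1 px, removes specks),
  and removal of components under 64 px.
* **Soma** (`segment_soma()`): nuclei seed the somas. The DAPI channel is
  thresholded, components under 30 px discarded, the surviving nuclei
  dilated by a disk (default radius 11 px ≈ the difference between a typical
  soma radius and its nucleus radius), and the result intersected with the
  neuron mask. This is the only construction consistent with building masks
  jointly from the B3T *and* DAPI channels, and it guarantees soma ⊆ neuron.
* **Neurite** (`derive_neurite()`): neuron minus soma, making the three
  compartments an exact partition. The set-algebra invariants
  (soma ∩ neurite = ∅, soma ∪ neurite = neuron) are asserted on every
  `build_masks()` result.

All radii and thresholds live in `seg_params()` and are recorded in each
mask set's provenance. Degenerate inputs return empty masks rather than
erroring (images with zero nuclei are legitimate — the study's nuclei counts
ranged down to 0), and downstream means over empty compartments are
reported as missing, never as zero.

```{r segmentation-example}
sc <- generate_scene(scene_spec(image_shape = c(128L, 128L), n_somas = 2L,
                                soma_radius_px = c(10, 14), seed = 1))
masks <- build_masks(sc$image, seg_params(nucleus_dilation_radius_px = 6L))
c(neuron = dice(masks$neuron, sc$truth$neuron_mask),
  soma = dice(masks$soma, sc$truth$soma_mask),
  neurite = dice(masks$neurite, sc$truth$neurite_mask))
```

## Intensity metrics

`mean_intensity()` is the arithmetic mean of a channel inside a mask,
computed in double precision and reported on the uint8 scale (0–255).
`elevated_area_fraction()` is the fraction of masked pixels strictly above
a threshold; since "elevated" has no published definition, the default rule
is a per-region Otsu threshold with a fixed-threshold override, and the rule
applied is always attached to the result. `max_intensity()` is the image-wide
channel maximum. `count_nuclei()` replaces the original CellProfiler step
with a self-contained counter (threshold → small-object removal →
distance-transform watershed), which keeps the pipeline dependency-free;
counts there served only as a covariate check. `growth_cone_metrics()`
encodes the activity definitions: events (extensions + retractions) per
minute, optionally normalised per filopodium (undefined at zero filopodia).

Every metric is tested for exact equality against per-pixel brute-force
loops on random fixtures, and the whole-image mean is checked to equal the
pixel-count-weighted mean over the soma/neurite/background partition.

## MEA spike and burst detection

`bandpass()` applies a 200–3000 Hz Butterworth band-pass, order 2 run
forward–backward (`signal::filtfilt`), i.e. an effective 4th-order zero-phase
filter. Zero phase matters because spike timestamps must not shift; 4th
order is standard offline practice. `detect_spikes()` estimates the noise SD
— robustly, via the scaled median absolute deviation, because spikes inflate
the plain SD; a plain-SD option is kept and the choice recorded — and marks
every excursion below −5 SD (configurable multiplier), timestamped at the
excursion's local minimum for stability against threshold jitter. A 1 ms
dead time suppresses double counting of multi-sample crossings; it is not
part of the original description but is required for a well-defined count.
`detect_bursts()` implements the 4-spikes-in-0.1-s (40 Hz) rule: every
window of 4 consecutive spikes spanning at most 0.1 s marks its spikes, and
maximal runs of marked spikes form bursts. `count_spikes()` uses the
half-open window [0, w), w = 300 s by default.

Detection is benchmarked against traces with embedded biphasic spikes
(sharp negative lobe, smaller delayed positive rebound; trough depth is
exactly the specified amplitude, so thresholds in noise-SD units are
meaningful). On pure noise, false detections are compared with the Rice
level-crossing rate of band-limited Gaussian noise, computed from the
designed filter's actual squared magnitude response
(`rice_crossing_rate()`); at −5 SD this predicts about two crossings per
five minutes for the 200–3000 Hz band.

## The statistical layer

Outcomes are analysed on a variance-stabilised scale
(`transform_spec()` / `apply_transform()`): Box-Cox with the exponent
estimated by profile maximum likelihood on a 0.01-step grid over [−2, 2],
plain log, or an integer root (the study used 4th and 6th roots for
particular outcomes). Exponents within 1e−5 of zero use the log limit to
avoid cancellation. Zeros on the uint8 scale get a +0.5 offset, carried inside the
`transform_spec()` object so the transform stays invertible.

Model fitting follows the study's ladder: a general linear model
(`fit_glm()`), a 2-level model with replicate random intercepts, and a
3-level model adding well within replicate (`fit_multilevel()`), all by
maximum likelihood so that `select_model()` can compare them by likelihood
ratio against the GLM and keep the simplest significant improvement.
Because a variance component's null value lies on its parameter-space
boundary, the LRT reference is the standard 50:50 chi-square mixture; ties
favour the simplest model. In the pipelines, once a multilevel model wins
the ladder it is refit by REML before estimation: ML variance estimates are
biased low in designs with a handful of replicates, and simulation of the
full imaging pipeline on null data shows that ML-based contrasts inflate
the family-wise error (about 0.11 at nominal 0.05) where the REML refit
keeps it controlled (about 0.06). Contrasts (`emmeans_contrasts()`) are pairwise
differences of estimated marginal means with Tukey adjustment; degrees of
freedom for mixed models come from the Kenward-Roger/Satterthwaite
machinery behind `emmeans`.

Counts from MEA recordings use `fit_zinb()`: a zero-inflated negative
binomial with log link on the count mean, culture day as a fixed covariate,
a group-by-stimulus interaction when stimuli are present, nested random
intercepts for replicate and electrode (Laplace approximation via glmmTMB),
and an intercept-only zero-inflation component — the simplest reading of
"zero-inflated", since the original does not say which covariates enter the
mixing probability. Marginal means average over the observed day
distribution. The closed-form ZINB likelihood (`zinb_loglik()`) is kept as
an independent check of the fitted objective. For outcomes that resist
transformation the non-parametric route is `kruskal_wallis_wilcoxon_bh()`
(tie-corrected Kruskal-Wallis, pairwise rank-sum tests without continuity
correction so the two-group case reproduces the omnibus p, BH adjustment
across the pairwise family), and `dose_response()` fits the ordinary
least-squares dose ladder with adjusted R².

```{r stats-example}
tb <- generate_table(table_spec(group_effects = c(control = 0, dosed = 1),
                                replicate_sd = 1, seed = 2))$table
fits <- list(fit_glm(tb),
             fit_multilevel(tb, levels = "replicate_only"),
             fit_multilevel(tb, levels = "replicate_and_well"))
sel <- select_model(fits)
attr(sel, "selection_table")
emmeans_contrasts(sel)$contrasts
```

## Pipelines, provenance and reproducibility

`run_imaging()` and `run_mea()` tie the stages together under a single
config (`imaging_config()` / `mea_config()`, or YAML via
`read_pipeline_config()`). All randomness flows from one base seed through
per-unit derived seeds, so identical configs reproduce identical outputs
byte for byte; each run emits a manifest with a config hash, output
checksums and accumulated warnings. Failures are isolated per image or
electrode — mirroring the per-unit structure of the study — and a run
aborts only if every unit fails. Degenerate ZINB fits (e.g. an all-silent
cohort) are reported as warnings with a `NULL` fit rather than failures.

## Problem sizes and what the benchmarks show

The package's benchmark suite fixes its study conditions once: segmentation
recovery on twenty 512×512 scenes at noise SD 15 (Dice thresholds 0.80 /
0.85 / 0.70 for neuron / soma / neurite); spike detection on 5-minute
25 kHz traces with twenty −10 SD spikes (sensitivity and precision ≥ 0.95,
timing within 1 ms); burst calling against a brute-force oracle on a
thousand random trains; ZINB recovery on a 6-replicate × 20-electrode ×
3-day design (effect 0.7 on the log mean, zero inflation 0.3, dispersion
1.5); mixed-model recovery at 6 × 4 × 10 with replicate SD 1 and well SD
0.5; and family-wise error of the full imaging pipeline on zero-effect
batches of 96×96 scenes (3 groups × 3 replicates × 2 wells × 2 images per
run). The acceptance script reruns the same computations at moderately
reduced seed counts (40 ZINB fits, 50 selection replicates, 100 pipeline
runs), sizes chosen to keep a full reproduction on a single CPU in the
minutes range while leaving Monte-Carlo error well inside the margins being
tested.

Known limitations: the segmentation defaults are stand-ins for the study's
unpublished MATLAB morphology code, so agreement with the original masks
cannot be asserted; the MEA detector's equivalence with the proprietary
MC_Rack implementation (its SD estimator and dead time are undocumented) is
likewise not claimed; and the synthetic generators' intensity and noise
levels are package choices, so passing benchmarks bound algorithmic
correctness, not real-data effect sizes.
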