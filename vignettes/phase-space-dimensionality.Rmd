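---
title: "Measuring the dimensionality of a convolutional network's phase space under spurious color-label correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the dimensionality of a convolutional network's phase space under spurious color-label correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

A cognitive system that encodes its environment through many independent
dimensions of meaning can discriminate nuance; a system whose encoding
collapses onto a few dominant dimensions interprets everything through the
same coarse lens. The harmonium model of psychopathology formalises this as
the dimensionality of a *phase space of meaning* (PSM): the claim is that
pathological cognition corresponds to a low-dimensional PSM dominated by a
couple of primary, affect-like dimensions, with little variance left for the
secondary, information-bearing ones.

`psmdim` operationalises that claim in a controlled simulation. Two copies of
the same small convolutional network (CNN) learn to classify colorized digit
images under two training environments that differ only in one statistical
property:

* **RC (random color)** — each training image receives one of six colors
  drawn uniformly and independently of the digit. Shape and color are
  orthogonal: the environment is high-dimensional.
* **FC (fixed color)** — color is a deterministic function of the digit
  (red for 0–1, cyan for 2–3, green for 4–5, magenta for 6–7, yellow for
  8–9; blue never occurs). Shape and color are fully confounded: the
  environment is low-dimensional, and color is a perfect shortcut.

Both networks are then evaluated on the *same* random-color test set,
defining the two conditions **RR** (random-trained, random-tested; the
"normotypical" proxy) and **FR** (fixed-trained, random-tested; the
"pathological" proxy). The FR network faces test images whose colors
contradict the rule it internalised, including a hue (blue) it never saw.

The analysis then treats each network's intermediate activations as its PSM
and asks how many principal components that space needs.

## Data

Two interchangeable greyscale sources feed the pipeline; both store images
as 28×28 matrices of *ink intensity* in [0, 1] (1 = full ink, 0 =
background) with digit labels 0–9.

1. `load_mnist_idx()` reads the standard IDX pair of the MNIST
   handwritten-digit database (magic numbers 2051/2049, big-endian), for
   full-scale runs when the files are available on disk.
2. `generate_glyph_dataset()` renders synthetic seven-segment-style digit
   skeletons, so the entire pipeline is testable without any download.

Colorization (`colorize()`) blends each pixel linearly between the white
background and the assigned color by its ink intensity:
$c_{ch} = (1-g)\cdot 1 + g\cdot \mathrm{color}_{ch}$. Grey levels become
saturation levels; the ink support is untouched; the background stays white.
This is the simplest map consistent with dark anti-aliased strokes on a
white background acquiring a hue, and we keep the anti-aliasing levels
rather than binarizing before coloring.

### What the glyph generator emulates — and what it does not

The generator reproduces the statistical structure the analysis relies on:
ten geometrically separable shape classes, continuous stroke intensities
(via anti-aliased rendering and Gaussian blur), within-class variability
(random rotation, translation and scale of the stroke skeleton, plus
additive pixel noise), and ink-on-white polarity. Its defaults (rotation
±20°, translation ±1.5 px, scale ±12%, stroke width 2.2 px, blur σ = 0.5 px,
noise σ = 0.10) were chosen so that (a) a nearest-centroid raw-pixel
baseline exceeds 0.8 accuracy on a 600/200 split — the classes are
trivially separable by shape, so any RR/FR contrast is attributable to the
color manipulation rather than unlearnable geometry — and (b) the
scaled-down CNN reaches the >95% test-accuracy regime in the RR condition.

It is *not* a handwriting model: glyphs share one skeleton per class, so
within-class variability is affine-plus-noise rather than stylistic, class
overlap is far lower than MNIST's (no ambiguous 4/9 or 3/5 pairs), and the
ink statistics are more homogeneous. Passing the scaled-down suite therefore
demonstrates that the pipeline detects the dimensionality consequences of a
color-confounded environment; it does not certify the exact index values
obtainable on MNIST.

## The network

`cnn_spec()` declares the fixed stack: three 3×3 valid (unpadded, stride-1)
convolutions of 32, 64 and 64 filters interleaved with 2×2 stride-2 max
pooling, a 576-to-64 dense layer, and a 10-way output; input 28×28×3. The
printed accounting — parameter counts 896 / 18,496 / 36,928 / 36,928 / 650
and shapes (26,26,32) → (13,13,32) → (11,11,64) → (5,5,64) → (3,3,64) → 576
→ 64 → 10 — follows analytically from those choices (`network_summary()`),
and the fitted weight arrays are asserted against it in the tests. The
hidden nonlinearities are rectified-linear and the output is a softmax; the
parameter accounting is independent of this choice, and ReLU + softmax is
the canonical configuration for this architecture. Valid padding and the
stride conventions are forced by the printed shapes (note the floor in
11 → 5).

Training (`train_network()`) minimises categorical cross-entropy on one-hot
labels with RMSprop (step 10⁻³, ρ = 0.9, ε = 10⁻⁷) and tracks accuracy. No
deep-learning framework is involved: the forward/backward passes (im2col
convolution, argmax-tracked pooling, softmax cross-entropy) and the RMSprop
update are implemented in compiled code inside the package, which keeps the
numerical core deterministic — all randomness (Glorot-uniform
initialization, epoch shuffles) flows from one R-side seed. Prediction ties
are broken toward the lowest class index; pooling ties toward the
first-scanned pixel (row-major).

## The dimensionality analysis

For each condition the three convolutional layers' post-ReLU outputs are
harvested over the shared test set (`extract_activations()`), at two
granularities:

* **pixel level** — every activation pixel of every filter is a feature:
  N = 21,632 / 7,744 / 576 per layer, 29,952 concatenated;
* **filter level** — each filter is summarised by the mean of its pixel
  activations per image: M = 32 / 64 / 64, 160 concatenated.

`run_pca()` mean-centers the features and computes the covariance
eigenspectrum — exactly (N ≤ 512) or through the singular values of the
centered matrix, which yields every non-null component when the sample
count is below the feature count; explained-variance ratios divide by the
total feature variance and are exact either way. Three indices summarise a
spectrum:

* **WPD** (weight of primary dimensions): cumulative explained variance of
  the first two components, in percent.
* **WSD** (weight of secondary dimensions): cumulative explained variance
  of components 3, 4, … whose eigenvalue strictly exceeds 1 — a Kaiser-like
  retention rule, with strict inequality. Reported at pixel level only; at
  filter level the secondary set is empty or a singleton and the index is
  uninformative.
* **D90**: the minimal number of leading components reaching 90% cumulative
  explained variance.

The eigenvalue-greater-than-one rule is classically defined on correlation
matrices, but standard PCA on activations is covariance-based; since the
choice is genuinely open we default to covariance (threshold applied to
covariance eigenvalues) and provide `pca_config("correlation")` — which
drops zero-variance features and standardises the rest — so both variants
can be reported side by side (driver `analysis/04_dimensionality.R` does).

The low-dimensionality hypothesis predicts, for FR relative to RR: higher
WPD, lower WSD, lower D90 — most strongly at the deepest layer and for all
layers pooled.

## Activation-intensity statistics

`compare_conditions()` tests, per layer scope, whether the FR and RR
networks spend different amounts of activation on the same test images. The
default sample unit is one value per (test image, filter) pair, which uses
every filter-mean the harvest produces (e.g. 160 × n values at the
all-layers scope); a per-image sensitivity mode (`unit = "image"`) averages
within images first. The test is Welch's unequal-variance two-sample t
(variance equality is visibly violated between conditions), FR first, so
positive t means FR activates more. The four tests (layers 1–3, all) are
jointly Benjamini–Hochberg corrected at α = 0.05.

## Scaled-down study conditions

The full-scale experiment (60,000/10,000 MNIST images, 5 epochs) needs the
MNIST download and tens of CPU-minutes. The package's default study conditions,
used by the tests, the acceptance script and the analysis drivers, are:
1,000 training and 600 test glyphs, 40 epochs, batch 64, PCA capped at 600
components (enough for every observed D90 with headroom, and above the
599-component rank limit of a 600-sample test set). Forty epochs ≈ 640
optimizer steps; with only ~16 batches per epoch the optimizer needs many
more epochs than the full-scale run to leave the under-trained regime, and
by 40 both networks sit in their terminal accuracy plateau (RR ≈ 1.0, FR ≈
1.0 on training data). One end-to-end run takes roughly three minutes on one
CPU core.

Under these conditions, across repeated seeds: the RR−FR test-accuracy gap
exceeds 0.5; WPD(FR) > WPD(RR) and D90(RR) > D90(FR) at both granularities;
and all four activation t-tests are significant after correction. One
full-scale directional pattern does *not* reproduce at this scale: the
*sign* of the activation-intensity difference. In the scaled-down synthetic
runs the RR network's mean filter activation is slightly *higher* than
FR's, whereas the low-dimensionality account predicts the pathological
proxy wastes more activation — the behaviour seen at full scale on MNIST.
The contrast magnitude shrinks with longer training in our
runs, but does not cross zero. We report this honestly rather than tuning
the generator toward the expected sign: the intensity direction appears to
depend on data statistics the glyph generator deliberately does not emulate
(MNIST's class overlap and stroke-statistics heterogeneity), not merely on
the color confound. The corresponding acceptance check is left failing,
with the directional dimensionality results — the core of the
low-dimensionality hypothesis — unaffected.

## Degenerate inputs and numerical conventions

* PCA refuses all-constant matrices and fewer than 3 samples; negative
  eigenvalue round-off is clamped to zero; spectra are sorted descending.
* `d90()` errors (rather than extrapolating) when retained components
  explain less than 90%, directing the caller to raise `max_components`.
* Identical inputs for both conditions produce exactly zero contrasts:
  t = 0, p = 1, identical indices, every directional flag "not held" — a
  property the tests assert as a negative control.
* Confusion matrices are row-normalized over occupied true-class rows;
  accuracy equals the label-frequency-weighted diagonal.
* Colorized datasets are byte-reproducible from their seeds; the RC color
  stream is one documented RNG stream per dataset build, so the RR and FR
  conditions share the test set bit-identically.

## Known limitations

* The compiled trainer implements exactly the canonical stack; it is a
  study instrument, not a general deep-learning library.
* Glyph simplicity caps how closely scaled-down index values can be
  expected to track full-scale MNIST values; only directions and orders of
  magnitude transfer.
* The activation-intensity sign divergence above.
* Pixel-level PCA at full scale (10,000 × 29,952) is memory-hungry
  (~2.4 GB for the concatenated matrix); the implementation favors
  correctness over streaming.
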