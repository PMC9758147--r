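# psmdim

Dimensionality of a convolutional network's internal representation under a
spurious color–label correlation — a simulation framework for the
low-dimensionality ("harmonium") account of general psychopathology, in
which pathological cognition corresponds to a phase space of meaning (PSM)
dominated by a few primary dimensions.

## The experiment

Two copies of one small CNN learn to classify colorized 28×28 digit images.
They differ only in the statistics of the training colors:

* **RC** (random color): one of six colors — red, green, blue, cyan,
  magenta, yellow — assigned uniformly at random, independent of the digit;
* **FC** (fixed color): color determined by the digit (red 0–1, cyan 2–3,
  green 4–5, magenta 6–7, yellow 8–9; blue unused), a perfect shortcut that
  collapses the training environment onto fewer independent dimensions.

Both networks are tested on the *same* random-color test set, giving the
conditions **RR** (random-trained) and **FR** (fixed-trained). The analysis
compares, between conditions:

1. **classification accuracy** and normalized confusion matrices;
2. **phase-space dimensionality**: PCA over the three convolutional layers'
   activations, at single-pixel granularity (N = 21,632 / 7,744 / 576 per
   layer, 29,952 pooled) and per-filter-mean granularity (M = 32 / 64 / 64,
   160 pooled), summarised by
   * `WPD` — explained variance of the first two components (%),
   * `WSD` — explained variance of components beyond the first two with
     eigenvalue > 1 (%), pixel level only,
   * `D90` — number of components reaching 90% explained variance;
3. **activation intensity**: Welch two-sample t-tests (FR vs RR) on
   per-(image, filter) mean activations per layer scope, jointly
   Benjamini–Hochberg corrected.

The network is the fixed stack conv3×3(32) → pool2×2 → conv3×3(64) →
pool2×2 → conv3×3(64) → flatten → dense(64) → dense(10, softmax) on
28×28×3 input (parameter counts 896 / 18,496 / 36,928 / 36,928 / 650),
trained with RMSprop on categorical cross-entropy. The trainer is
implemented in the package (RcppArmadillo); no external deep-learning
framework is required. Greyscale digits come either from MNIST IDX files
(`load_mnist_idx()`) or from a built-in seven-segment glyph generator
(`generate_glyph_dataset()`), so everything below runs with no download.

## Worked example

```r
library(psmdim)

report <- run_experiment(experiment_config(seed_data = 1, seed_train = 101))
render_report(report)
```

The default (scaled-down) conditions use 1,000 training and 600 test
glyphs and 40 epochs; one run takes about three minutes on one CPU. The run
above prints, among other things:

```
Accuracy: RR 0.9950 | FR 0.2250

Dimensionality, pixel level
  scope condition   wpd   wsd n_secondary d90
3     3        RR 43.38 53.33          21  11
4   all        RR 32.57 62.88          57  25
7     3        FR 75.15 22.52          16   6
8   all        FR 64.14 31.58          45  19
```

Reading: the fixed-color-trained network scores barely above the 0.1
random baseline on random-color test images (it learned the color
shortcut), and its activation space is markedly lower-dimensional — the
first two components carry 64% of the variance against 33% for the
random-trained network, which needs 25 components to cover 90% of its
variance against 19. The same contrast appears at filter level, and all
four FDR-corrected intensity tests are significant. The directional
flags at the end of the report mark which of these patterns held in the
current run.

The numbered drivers under `analysis/` stage the same computation
(architecture accounting, dataset simulation, training, dimensionality
tables including a correlation-PCA variant, activation statistics) and
write their tables under `results/`.

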