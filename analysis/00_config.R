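# Shared configuration for the analysis drivers 01-05.
# Scaled-down study conditions: 1,000 training and 600 test glyphs,
# 40 training epochs; seeds fixed for reproducibility.

library(psmdim)

analysis_config <- function(seed_data = 1L, seed_train = 101L) {
  experiment_config(
    data_source = "synthetic",
    n_train = 1000L, n_test = 600L,
    training = training_config(epochs = 40L),
    pca = pca_config(max_components = 600L),
    seed_data = seed_data, seed_train = seed_train
  )
}

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}

scratch_dir <- function() {
  dir.create("scratch", showWarnings = FALSE)
  "scratch"
}
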