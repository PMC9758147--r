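#!/usr/bin/env Rscript
# Phase-space dimensionality of the two trained networks: PCA over
# intermediate activations of the three convolutional layers at pixel and
# filter granularity; indices WPD (weight of the first two components), WSD
# (components beyond the first two with eigenvalue > 1; pixel level only)
# and D90 (components to reach 90% explained variance).
# Finding: the fixed-color-trained (FR) network occupies a lower-dimensional
# phase space — higher WPD, lower WSD and lower D90 than RR, most visibly at
# the deepest layer and for all layers pooled.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_config.R"))

data <- readRDS(file.path(scratch_dir(), "datasets.rds"))
nets <- readRDS(file.path(scratch_dir(), "networks.rds"))

for (level in c("pixel", "filter")) {
  tab <- dimensionality_table(nets$net_rr, nets$net_fr, data$test_rc,
    level = level, config = data$cfg$pca
  )
  cat("\n==", level, "level ==\n")
  print(tab, digits = 4)
  write.csv(tab, file.path(results_dir(), paste0("dimensionality_", level, ".csv")),
    row.names = FALSE
  )
}

# correlation-matrix variant of the pixel-level analysis, for comparison
tab_cor <- dimensionality_table(nets$net_rr, nets$net_fr, data$test_rc,
  level = "pixel", config = pca_config("correlation", max_components = 600L)
)
cat("\n== pixel level, correlation PCA ==\n")
print(tab_cor, digits = 4)
write.csv(tab_cor, file.path(results_dir(), "dimensionality_pixel_correlation.csv"),
  row.names = FALSE
)
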