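#!/usr/bin/env Rscript
# Architecture accounting: the layer stack, its output shapes and trainable
# parameter counts, derived analytically from the declarative spec.
# Finding: the stack yields the expected accounting exactly —
# 896 / 18,496 / 36,928 / 36,928 / 650 parameters and shapes
# (26,26,32)->(13,13,32)->(11,11,64)->(5,5,64)->(3,3,64)->576->64->10.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_config.R"))

tab <- network_summary(cnn_spec())
print(tab)
cat("total trainable parameters:", attr(tab, "total_params"), "\n")

write.csv(tab, file.path(results_dir(), "architecture.csv"), row.names = FALSE)
cat("wrote", file.path(results_dir(), "architecture.csv"), "\n")
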