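#!/usr/bin/env Rscript
# Simulate the study datasets: greyscale glyphs, then three colorized sets —
# a random-color (RC) training set, a fixed-color (FC) training set built
# from the same greyscale images, and one shared RC test set.
# Finding: in the FC set color is a function of the digit (5 of 6 palette
# colors used, blue absent); in the RC sets color is uniform and carries no
# label information.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_config.R"))

cfg <- analysis_config()
grey <- psmdim:::load_greyscale(cfg)
cat("greyscale pools:", length(grey$train$labels), "train,", length(grey$test$labels), "test\n")

baseline <- nearest_centroid_accuracy(grey$train, grey$test)
cat("nearest-centroid baseline on raw pixels:", round(baseline, 3), "\n")

train_rc <- build_colored_dataset(grey$train, color_assignment("RC"), seed = cfg$seed_data + 101L)
train_fc <- build_colored_dataset(grey$train, color_assignment("FC"), seed = cfg$seed_data + 101L)
test_rc <- build_colored_dataset(grey$test, color_assignment("RC"), seed = cfg$seed_data + 202L)

for (nm in c("train_rc", "train_fc", "test_rc")) {
  ds <- get(nm)
  man <- dataset_manifest(ds)
  write.csv(man, file.path(results_dir(), paste0("manifest_", nm, ".csv")),
    row.names = FALSE
  )
  cat(nm, ": colors used =", paste(sort(unique(ds$color_id)), collapse = ","), "\n")
}

ct <- table(train_rc$labels, train_rc$color_id)
cat(
  "RC label-color association (chi-square p):",
  round(suppressWarnings(chisq.test(ct))$p.value, 3), "\n"
)

saveRDS(
  list(cfg = cfg, train_rc = train_rc, train_fc = train_fc, test_rc = test_rc,
       baseline = baseline),
  file.path(scratch_dir(), "datasets.rds")
)
cat("wrote", file.path(scratch_dir(), "datasets.rds"), "\n")
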