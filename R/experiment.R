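#' Configuration of one two-condition experiment
#'
#' Describes everything needed to reproduce a run: the greyscale digit
#' source, how many images enter training and test, the training and PCA
#' settings, and the seeds for dataset construction and training. The same
#' underlying greyscale images feed both conditions, and one random-color
#' test set is shared bit-identically between them.
#'
#' @param data_source `"synthetic"` (built-in glyph generator) or `"mnist"`
#'   (IDX files on disk).
#' @param n_train,n_test Number of training and test images.
#' @param glyph A [glyph_params()] template for the synthetic source; its
#'   `n_per_class` and `seed` are overridden from `n_train`/`n_test` and
#'   `seed_data`.
#' @param mnist_dir Directory holding the four standard IDX files (used only
#'   when `data_source = "mnist"`).
#' @param training A [training_config()]; its seed is overridden by
#'   `seed_train`.
#' @param pca A [pca_config()].
#' @param seed_data Seed for glyph generation and color assignment.
#' @param seed_train Seed for weight initialization and batch shuffling.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(data_source = c("synthetic", "mnist"),
                              n_train = 1000L, n_test = 600L,
                              glyph = glyph_params(),
                              mnist_dir = NULL,
                              training = training_config(epochs = 40L),
                              pca = pca_config(max_components = 600L),
                              seed_data = 1L, seed_train = 1L) {
  data_source <- match.arg(data_source)
  stopifnot(n_train >= 10, n_test >= 10)
  structure(
    list(
      data_source = data_source, n_train = as.integer(n_train),
      n_test = as.integer(n_test), glyph = glyph, mnist_dir = mnist_dir,
      training = training, pca = pca,
      seed_data = as.integer(seed_data), seed_train = as.integer(seed_train)
    ),
    class = "experiment_config"
  )
}

# Greyscale train/test pools for a config.
load_greyscale <- function(config) {
  if (config$data_source == "synthetic") {
    params <- config$glyph
    params$n_per_class <- as.integer(ceiling((config$n_train + config$n_test) / 10))
    params$seed <- config$seed_data
    pool <- generate_glyph_dataset(params)
    idx_train <- seq_len(config$n_train)
    idx_test <- config$n_train + seq_len(config$n_test)
    list(
      train = subset_grey(pool, idx_train),
      test = subset_grey(pool, idx_test)
    )
  } else {
    if (is.null(config$mnist_dir)) stop("mnist_dir is required for the mnist source")
    train <- load_mnist_idx(
      file.path(config$mnist_dir, "train-images-idx3-ubyte"),
      file.path(config$mnist_dir, "train-labels-idx1-ubyte")
    )
    test <- load_mnist_idx(
      file.path(config$mnist_dir, "t10k-images-idx3-ubyte"),
      file.path(config$mnist_dir, "t10k-labels-idx1-ubyte")
    )
    list(
      train = subset_grey(train, seq_len(min(config$n_train, length(train$labels)))),
      test = subset_grey(test, seq_len(min(config$n_test, length(test$labels))))
    )
  }
}

subset_grey <- function(ds, idx) {
  structure(
    list(images = ds$images[idx, , , drop = FALSE], labels = ds$labels[idx]),
    class = "grey_digits"
  )
}

#' Run the full two-condition experiment
#'
#' Builds a random-color (RC) training set, a fixed-color (FC) training set
#' from the same greyscale images, and one shared RC test set; trains one
#' network per condition with identical settings; evaluates both on the
#' shared test set; and runs the three comparison analyses (pixel-level and
#' filter-level dimensionality tables, activation-intensity t-tests).
#'
#' @param config An [experiment_config()].
#' @param verbose Print per-stage progress to stderr.
#' @return An `experiment_report`: list with `config`, `config_hash`,
#'   `evaluation` (per condition), `pixel_table`, `filter_table`,
#'   `activation_stats`, `flags` (directional patterns), `history` (training
#'   curves), `session` (provenance).
#' @export
run_experiment <- function(config = experiment_config(), verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message("[psmdim] ", ...)

  say("building datasets (", config$data_source, ")")
  grey <- load_greyscale(config)
  rc <- color_assignment("RC")
  fc <- color_assignment("FC")
  train_rc <- build_colored_dataset(grey$train, rc, seed = config$seed_data + 101L)
  train_fc <- build_colored_dataset(grey$train, fc, seed = config$seed_data + 101L)
  test_rc <- build_colored_dataset(grey$test, rc, seed = config$seed_data + 202L)

  tcfg <- config$training
  tcfg$seed <- config$seed_train
  say("training RR network (", tcfg$epochs, " epochs)")
  net_rr <- train_network(cnn_spec(), train_rc, tcfg)
  say("training FR network")
  net_fr <- train_network(cnn_spec(), train_fc, tcfg)

  say("evaluating on the shared RC test set")
  eval_rr <- evaluate_network(net_rr, test_rc)
  eval_fr <- evaluate_network(net_fr, test_rc)

  say("harvesting activations and running PCA")
  pixel_rr <- condition_features(net_rr, test_rc, "pixel")
  pixel_fr <- condition_features(net_fr, test_rc, "pixel")
  filt_rr <- condition_features(net_rr, test_rc, "filter")
  filt_fr <- condition_features(net_fr, test_rc, "filter")
  pixel_table <- scope_table(list(RR = pixel_rr, FR = pixel_fr), "pixel", config$pca)
  filter_table <- scope_table(list(RR = filt_rr, FR = filt_fr), "filter", config$pca)

  say("activation-intensity t-tests")
  stats <- compare_conditions(filt_rr[1:3], filt_fr[1:3])

  all_px <- function(tab, cond, col) tab[tab$scope == "all" & tab$condition == cond, col]
  flags <- list(
    accuracy_rr_gt_fr = eval_rr$accuracy > eval_fr$accuracy,
    wpd_fr_gt_rr_pixel = all_px(pixel_table, "FR", "wpd") > all_px(pixel_table, "RR", "wpd"),
    wpd_fr_gt_rr_filter = all_px(filter_table, "FR", "wpd") > all_px(filter_table, "RR", "wpd"),
    d90_rr_gt_fr_pixel = all_px(pixel_table, "RR", "d90") > all_px(pixel_table, "FR", "d90"),
    d90_rr_gt_fr_filter = all_px(filter_table, "RR", "d90") > all_px(filter_table, "FR", "d90"),
    activation_fr_gt_rr = all(stats$mean_fr > stats$mean_rr),
    all_tests_significant = all(stats$significant)
  )

  report <- structure(
    list(
      config = config,
      config_hash = fnv1a_hash(deparse(config[setdiff(names(config), "glyph")])),
      evaluation = list(RR = eval_rr, FR = eval_fr),
      pixel_table = pixel_table,
      filter_table = filter_table,
      activation_stats = stats,
      flags = flags,
      history = list(RR = net_rr$history, FR = net_fr$history),
      networks = list(RR = net_rr, FR = net_fr),
      session = list(
        r_version = R.version.string,
        package_version = as.character(utils::packageVersion("psmdim")),
        seed_data = config$seed_data, seed_train = config$seed_train
      )
    ),
    class = "experiment_report"
  )
  say("done; RR accuracy ", sprintf("%.4f", eval_rr$accuracy), ", FR accuracy ",
    sprintf("%.4f", eval_fr$accuracy))
  report
}

#' Render an experiment report as a readable summary
#'
#' Prints the two confusion matrices, the dimensionality tables at both
#' granularities, the activation t-test table, and whether each directional
#' pattern held in this run.
#'
#' @param report An `experiment_report` from [run_experiment()].
#' @return `report`, invisibly.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  cat("== Experiment report (config ", report$config_hash, ") ==\n", sep = "")
  cat(
    "Accuracy: RR", sprintf("%.4f", report$evaluation$RR$accuracy),
    "| FR", sprintf("%.4f", report$evaluation$FR$accuracy), "\n\n"
  )
  for (cond in c("RR", "FR")) {
    cat("Normalized confusion matrix,", cond, "\n")
    print(round(report$evaluation[[cond]]$confusion, 2))
    cat("\n")
  }
  cat("Dimensionality, pixel level\n")
  print(report$pixel_table, digits = 4)
  cat("\nDimensionality, filter level\n")
  print(report$filter_table[, c("scope", "condition", "wpd", "d90")], digits = 4)
  cat("\nActivation-intensity comparison (FR vs RR)\n")
  print(as.data.frame(report$activation_stats)[, c(
    "scope", "t", "df", "p_uncorrected", "p_fdr", "significant"
  )], digits = 4)
  cat("\nDirectional patterns:\n")
  for (nm in names(report$flags)) {
    cat(sprintf(
      "  %-24s %s\n", nm,
      if (isTRUE(report$flags[[nm]])) "held" else "not held"
    ))
  }
  invisible(report)
}

#' @export
print.experiment_report <- function(x, ...) render_report(x)

#' Write an experiment report to disk
#'
#' JSON-canonical report with CSV mirrors of the three tables, written
#' atomically (to a temporary name, then renamed).
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    config_hash = report$config_hash,
    session = report$session,
    accuracy = list(
      RR = report$evaluation$RR$accuracy,
      FR = report$evaluation$FR$accuracy
    ),
    confusion = list(
      RR = report$evaluation$RR$confusion,
      FR = report$evaluation$FR$confusion
    ),
    pixel_table = report$pixel_table,
    filter_table = report$filter_table,
    activation_stats = as.data.frame(report$activation_stats),
    flags = report$flags
  )
  tmp <- tempfile(tmpdir = dir, fileext = ".json")
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, file.path(dir, "report.json"))
  for (nm in c("pixel_table", "filter_table", "activation_stats")) {
    tmp <- tempfile(tmpdir = dir, fileext = ".csv")
    utils::write.csv(as.data.frame(report[[nm]]), tmp, row.names = FALSE)
    file.rename(tmp, file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}
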