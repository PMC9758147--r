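# Shared fixtures, built in code. Heavy objects are memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Write a tiny IDX image/label pair (big-endian, MNIST layout) and return the
# two paths. `mangle` lets tests corrupt specific aspects.
write_idx_fixture <- function(dir, n = 12L,
                              mangle = c("none", "magic", "count", "truncate")) {
  mangle <- match.arg(mangle)
  set.seed(99)
  labels <- as.integer((seq_len(n) - 1L) %% 10L)
  pixels <- as.raw(sample.int(256L, n * 28L * 28L, replace = TRUE) - 1L)

  be_int <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "big")
  img_magic <- if (mangle == "magic") 1234L else 2051L
  img <- c(be_int(img_magic), be_int(n), be_int(28L), be_int(28L), pixels)
  if (mangle == "truncate") img <- img[seq_len(length(img) - 100L)]
  lab_n <- if (mangle == "count") n + 3L else n
  lab <- c(be_int(2049L), be_int(lab_n), as.raw(labels))
  if (mangle == "count") lab <- c(lab, as.raw(rep(0L, 3L)))

  ipath <- file.path(dir, "images-idx3-ubyte")
  lpath <- file.path(dir, "labels-idx1-ubyte")
  writeBin(img, ipath)
  writeBin(lab, lpath)
  list(images = ipath, labels = lpath, n = n, labels_true = labels,
       pixels_raw = pixels)
}

# A small trained network plus datasets, enough for activation-shape and
# evaluation tests without a full experiment.
tiny_trained <- function() {
  memo("tiny_trained", {
    grey <- generate_glyph_dataset(glyph_params(n_per_class = 8L, seed = 21L))
    train <- build_colored_dataset(grey, color_assignment("RC"), seed = 31L)
    net <- train_network(
      cnn_spec(), train,
      training_config(epochs = 2L, batch_size = 16L, seed = 41L)
    )
    test_grey <- generate_glyph_dataset(glyph_params(n_per_class = 3L, seed = 22L))
    test <- build_colored_dataset(test_grey, color_assignment("RC"), seed = 32L)
    list(net = net, train = train, test = test)
  })
}

# The scaled-down five-seed replication suite shared by the acceptance tests.
replication_suite <- function() {
  memo("replication_suite", {
    lapply(1:5, function(s) {
      run_experiment(
        experiment_config(seed_data = s, seed_train = 100L + s),
        verbose = FALSE
      )
    })
  })
}
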