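test_that("palette has six saturated RGB colors and the fixed map pairs digits", {
  pal <- color_palette()
  expect_equal(nrow(pal), 6L)
  expect_setequal(pal$name, c("red", "green", "blue", "cyan", "magenta", "yellow"))
  expect_true(all(as.matrix(pal[, c("r", "g", "b")]) %in% c(0, 1)))

  map <- fixed_color_map()
  expect_equal(length(map), 10L)
  expect_equal(pal$name[map[["0"]]], "red")
  expect_equal(pal$name[map[["1"]]], "red")
  expect_equal(pal$name[map[["2"]]], "cyan")
  expect_equal(pal$name[map[["5"]]], "green")
  expect_equal(pal$name[map[["7"]]], "magenta")
  expect_equal(pal$name[map[["9"]]], "yellow")
  # blue never occurs under the fixed assignment
  expect_false("blue" %in% pal$name[map])
  expect_equal(length(unique(map)), 5L)
})

test_that("colorize blends linearly between white and the assigned color", {
  blank <- matrix(0, 28, 28)
  out <- colorize(blank, c(1, 0, 0))
  expect_equal(dim(out), c(28L, 28L, 3L))
  expect_true(all(out == 1)) # background stays white

  full <- matrix(1, 2, 2)
  expect_true(all(colorize(full, c(1, 0, 0))[, , 1] == 1))
  expect_true(all(colorize(full, c(1, 0, 0))[, , 2] == 0))

  half <- matrix(0.5, 1, 1)
  expect_equal(as.numeric(colorize(half, c(1, 0, 0))), c(1, 0.5, 0.5))

  expect_error(colorize(matrix(1.5, 1, 1), c(1, 0, 0)), "\\[0, 1\\]")
})

test_that("colorization preserves the ink support and round-trips at 8-bit depth", {
  set.seed(5)
  for (rep in 1:5) {
    g <- matrix(runif(784) * (runif(784) > 0.6), 28, 28)
    color <- as.numeric(color_palette()[sample.int(6, 1), c("r", "g", "b")])
    rgb <- colorize(g, color)
    # a pixel carries ink iff some channel departs from white
    ink_after <- apply(rgb < 1, c(1, 2), any)
    expect_equal(ink_after, g > 0)
    # 8-bit quantization round-trip
    q <- round(rgb * 255) / 255
    expect_true(max(abs(q - rgb)) <= 1 / 510)
  }
})

test_that("assign_color honors FC lookups and RC uniformity", {
  img <- matrix(0.5, 28, 28)
  fc <- color_assignment("FC")
  expect_equal(color_palette()$name[assign_color(img, 0, fc)$color_id], "red")
  expect_equal(color_palette()$name[assign_color(img, 9, fc)$color_id], "yellow")
  expect_error(assign_color(img, 11, fc), "0..9")

  # RC draws: each color frequency within 3 binomial sds of 1/6
  n <- 60000L
  grey <- structure(
    list(images = array(0.5, c(n, 2, 2)), labels = rep.int(0:9, n / 10)),
    class = "grey_digits"
  )
  rc_ds <- build_colored_dataset(grey, color_assignment("RC"), seed = 123)
  freq <- tabulate(rc_ds$color_id, 6) / n
  tol <- 3 * sqrt((1 / 6) * (5 / 6) / n)
  expect_true(all(abs(freq - 1 / 6) < tol))
})

test_that("dataset builds are deterministic and color carries no label information in RC mode", {
  grey <- generate_glyph_dataset(glyph_params(n_per_class = 10L, seed = 7L))
  a <- build_colored_dataset(grey, color_assignment("RC"), seed = 11)
  b <- build_colored_dataset(grey, color_assignment("RC"), seed = 11)
  expect_identical(a, b)

  fc_ds <- build_colored_dataset(grey, color_assignment("FC"), seed = 11)
  # FC: color_id is a function of the label alone; exactly 5 of 6 colors occur
  expect_true(all(tapply(fc_ds$color_id, fc_ds$labels, function(x) length(unique(x))) == 1L))
  expect_equal(length(unique(fc_ds$color_id)), 5L)

  # RC at large n: plug-in mutual information between label and color ~ 0
  n <- 30000L
  big <- structure(
    list(images = array(0, c(n, 2, 2)), labels = rep.int(0:9, n / 10)),
    class = "grey_digits"
  )
  rc_ds <- build_colored_dataset(big, color_assignment("RC"), seed = 5)
  joint <- table(rc_ds$labels, rc_ds$color_id) / n
  mi <- sum(joint * log(joint / (rowSums(joint) %o% colSums(joint))), na.rm = TRUE)
  expect_lt(mi, 0.01)
  expect_equal(length(unique(rc_ds$color_id)), 6L)

  # manifest mirrors the dataset
  man <- dataset_manifest(fc_ds)
  expect_equal(names(man), c("index", "label", "color_id"))
  expect_equal(man$color_id, fc_ds$color_id)
})
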