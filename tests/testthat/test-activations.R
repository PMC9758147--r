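test_that("activation tensors have the declared per-layer shapes and are non-negative", {
  fx <- tiny_trained()
  n <- length(fx$test$labels)
  shapes <- list(c(26L, 26L, 32L), c(11L, 11L, 64L), c(3L, 3L, 64L))
  for (l in 1:3) {
    a <- extract_activations(fx$net, fx$test, l)
    expect_equal(dim(a), c(n, shapes[[l]]))
    expect_true(all(a >= 0)) # rectified-linear outputs
  }
  expect_error(extract_activations(fx$net, fx$test, 4), "layer_index")
})

test_that("activations are invariant to batch composition", {
  fx <- tiny_trained()
  single <- structure(
    list(
      images = fx$test$images[3, , , , drop = FALSE],
      labels = fx$test$labels[3], color_id = fx$test$color_id[3],
      assignment = fx$test$assignment, seed = fx$test$seed
    ),
    class = "colored_digits"
  )
  for (l in 1:3) {
    batch <- extract_activations(fx$net, fx$test, l)
    alone <- extract_activations(fx$net, single, l)
    expect_equal(alone[1, , , ], batch[3, , , ], tolerance = 1e-5)
  }
})

test_that("pixel flattening yields the published feature counts and is a bijection", {
  fx <- tiny_trained()
  tensors <- lapply(1:3, function(l) extract_activations(fx$net, fx$test, l))
  mats <- lapply(tensors, flatten_pixels)
  expect_equal(vapply(mats, ncol, integer(1)), c(21632L, 7744L, 576L))
  all_mat <- concat_scopes(mats)
  expect_equal(ncol(all_mat), 29952L)
  expect_equal(attr(all_mat, "layer_scope"), "all")

  for (l in 1:3) {
    back <- unflatten_pixels(mats[[l]])
    expect_equal(unclass(back), unclass(tensors[[l]]), ignore_attr = TRUE)
  }

  # documented feature order: filter index varies fastest, then column, then row
  a <- tensors[[3]]
  m <- mats[[3]]
  expect_equal(m[2, 1:64], a[2, 1, 1, ], ignore_attr = TRUE)
  expect_equal(m[2, 65:128], a[2, 1, 2, ], ignore_attr = TRUE)
})

test_that("filter means match direct recomputation and the published widths", {
  fx <- tiny_trained()
  tensors <- lapply(1:3, function(l) extract_activations(fx$net, fx$test, l))
  fm <- lapply(tensors, filter_means)
  expect_equal(vapply(fm, ncol, integer(1)), c(32L, 64L, 64L))
  expect_equal(ncol(concat_scopes(fm)), 160L)

  # entry (i, f) is the mean over the filter's pixels for that image
  a <- tensors[[2]]
  expect_equal(fm[[2]][5, 7], mean(a[5, , , 7]), tolerance = 1e-6)
  expect_equal(fm[[2]][1, ], apply(a[1, , , ], 3, mean),
    tolerance = 1e-6, ignore_attr = TRUE
  )

  # constant tensor: every mean equals the constant
  const <- structure(array(0.37, c(4, 3, 3, 5)),
    layer_index = 3L,
    class = c("activation_tensor", "array")
  )
  expect_true(all(filter_means(const) == 0.37))
})

test_that("concatenation preserves order and rejects mismatched sample counts", {
  m1 <- matrix(1:6, 2)
  m2 <- matrix(7:10, 2)
  out <- concat_scopes(list(m1, m2))
  expect_equal(unclass(out)[, 1:3], m1, ignore_attr = TRUE)
  expect_equal(unclass(out)[, 4:5], m2, ignore_attr = TRUE)
  # a single matrix passes through unchanged
  expect_equal(unclass(concat_scopes(list(m1))), m1, ignore_attr = TRUE)
  expect_error(concat_scopes(list(m1, matrix(1:9, 3))), "mismatch")
})
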