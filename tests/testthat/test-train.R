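test_that("training reduces the loss and is reproducible given the seed", {
  grey <- generate_glyph_dataset(glyph_params(n_per_class = 4L, seed = 51L))
  ds <- build_colored_dataset(grey, color_assignment("RC"), seed = 52L)
  cfg <- training_config(epochs = 3L, batch_size = 8L, seed = 53L)
  net <- train_network(cnn_spec(), ds, cfg)
  expect_s3_class(net, "trained_network")
  expect_equal(nrow(net$history), 3L)
  # early epochs: running training loss goes down
  expect_lt(net$history$loss[2], net$history$loss[1])
  expect_lte(net$history$loss[3], net$history$loss[2])

  net2 <- train_network(cnn_spec(), ds, cfg)
  expect_identical(net$weights, net2$weights)
  expect_identical(net$history, net2$history)
})

test_that("predictions are valid probability distributions", {
  fx <- tiny_trained()
  probs <- predict(fx$net, fx$test, type = "prob")
  expect_equal(dim(probs), c(length(fx$test$labels), 10L))
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-5)
  cls <- predict(fx$net, fx$test, type = "class")
  expect_true(all(cls %in% 0:9))
  expect_equal(cls, max.col(probs, ties.method = "first") - 1L)
})

test_that("one-hot encoding is exact", {
  oh <- one_hot(c(0L, 9L, 3L))
  expect_equal(dim(oh), c(3L, 10L))
  expect_equal(rowSums(oh), rep(1L, 3))
  expect_equal(which(oh[2, ] == 1L), 10L)
  expect_error(one_hot(c(0L, 12L)))
})

test_that("evaluation yields accuracy and a row-normalized confusion matrix", {
  labels <- rep.int(0:9, 5)
  # oracle predictor: identity confusion, accuracy 1
  oracle <- classification_report(labels, labels)
  expect_equal(oracle$accuracy, 1)
  expect_equal(unname(oracle$confusion), diag(10))

  # constant predictor on a balanced set: accuracy = 1/10
  const <- classification_report(labels, rep.int(7L, length(labels)))
  expect_equal(const$accuracy, 0.1)
  expect_equal(unname(rowSums(const$confusion)), rep(1, 10), tolerance = 1e-9)

  # accuracy equals the label-frequency-weighted confusion diagonal
  set.seed(8)
  pred <- sample(0:9, length(labels), replace = TRUE)
  rpt <- classification_report(labels, pred)
  wts <- as.numeric(table(factor(labels, levels = 0:9))) / length(labels)
  expect_equal(rpt$accuracy, sum(wts * diag(rpt$confusion)))

  expect_error(classification_report(integer(0), integer(0)), "empty")
})

test_that("network evaluation runs end-to-end on a held-out set", {
  fx <- tiny_trained()
  ev <- evaluate_network(fx$net, fx$test)
  expect_s3_class(ev, "evaluation_result")
  expect_gte(ev$accuracy, 0)
  expect_lte(ev$accuracy, 1)
  occupied <- rowSums(ev$confusion) > 0
  expect_equal(unname(rowSums(ev$confusion)[occupied]),
    rep(1, sum(occupied)),
    tolerance = 1e-9
  )
})
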