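#' Training configuration
#'
#' Categorical cross-entropy loss on one-hot labels, RMSprop optimizer, and
#' accuracy as the monitored metric are fixed; epochs, batch size and the
#' optimizer's numeric knobs are tunable.
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size.
#' @param learning_rate RMSprop step size.
#' @param rho RMSprop moving-average decay for the squared gradients.
#' @param epsilon RMSprop denominator stabiliser.
#' @param seed Integer seed controlling weight initialization and epoch
#'   shuffling.
#' @return A `training_config` object.
#' @export
training_config <- function(epochs = 5L, batch_size = 64L,
                            learning_rate = 1e-3, rho = 0.9, epsilon = 1e-7,
                            seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, rho > 0, rho < 1)
  structure(
    list(
      loss = "categorical_crossentropy", optimizer = "rmsprop",
      metric = "accuracy", epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), learning_rate = learning_rate,
      rho = rho, epsilon = epsilon, seed = as.integer(seed)
    ),
    class = "training_config"
  )
}

#' One-hot encode digit labels
#'
#' @param labels Integer vector in 0..9.
#' @return An `n x 10` 0/1 matrix.
#' @export
one_hot <- function(labels) {
  stopifnot(all(labels %in% 0:9))
  out <- matrix(0L, length(labels), 10L)
  out[cbind(seq_along(labels), labels + 1L)] <- 1L
  out
}

# Glorot-uniform initialization; the receptive-field fan convention for conv
# kernels, plain fan-in/out for dense layers. Uses the current RNG stream.
init_weights <- function() {
  glorot <- function(nr, nc, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  list(
    W1 = glorot(27, 32, 9 * 3, 9 * 32), b1 = numeric(32),
    W2 = glorot(288, 64, 9 * 32, 9 * 64), b2 = numeric(64),
    W3 = glorot(576, 64, 9 * 64, 9 * 64), b3 = numeric(64),
    W4 = glorot(576, 64, 576, 64), b4 = numeric(64),
    W5 = glorot(64, 10, 64, 10), b5 = numeric(10)
  )
}

#' Train the canonical CNN on a colorized digit dataset
#'
#' Minimises categorical cross-entropy with RMSprop over shuffled
#' mini-batches. All randomness (weight initialization, per-epoch shuffles)
#' is drawn from one stream seeded by `config$seed`, so a run is fully
#' reproducible; the compiled numerical core is deterministic.
#'
#' @param spec A [cnn_spec()]; only the canonical stack is trainable.
#' @param dataset A `colored_digits` training set.
#' @param config A [training_config()].
#' @return A `trained_network` object with elements `spec`, `weights`,
#'   `history` (per-epoch data frame of running training loss and accuracy),
#'   and `config`.
#' @export
train_network <- function(spec, dataset, config = training_config()) {
  assert_canonical_spec(spec)
  stopifnot(inherits(dataset, "colored_digits"), inherits(config, "training_config"))
  n <- length(dataset$labels)
  if (n < config$batch_size) {
    warning("fewer images than one batch; using a single batch of size ", n)
  }
  fit <- with_seed(config$seed, {
    w0 <- init_weights()
    orders <- t(vapply(
      seq_len(config$epochs), function(e) sample.int(n),
      integer(n)
    ))
    cnn_train_cpp(
      dataset$images, as.integer(dataset$labels), w0, orders,
      config$batch_size, config$learning_rate, config$rho, config$epsilon
    )
  })
  structure(
    list(
      spec = spec, weights = fit$weights,
      history = data.frame(
        epoch = seq_len(config$epochs),
        loss = as.numeric(fit$loss),
        accuracy = as.numeric(fit$accuracy)
      ),
      config = config
    ),
    class = "trained_network"
  )
}

#' @export
print.trained_network <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(
    "<trained_network>", nrow(x$history), "epochs; final training loss",
    sprintf("%.4f", last$loss), "accuracy", sprintf("%.4f", last$accuracy), "\n"
  )
  invisible(x)
}

#' Predict class probabilities or labels
#'
#' @param object A `trained_network`.
#' @param dataset A `colored_digits` dataset.
#' @param type `"prob"` for the `n x 10` softmax matrix, `"class"` for argmax
#'   digit labels (ties broken toward the lowest class index).
#' @param ... Unused.
#' @return A probability matrix or an integer label vector.
#' @export
predict.trained_network <- function(object, dataset, type = c("prob", "class"),
                                    ...) {
  type <- match.arg(type)
  stopifnot(inherits(dataset, "colored_digits"))
  probs <- cnn_forward_cpp(dataset$images, object$weights, FALSE)$probs
  if (type == "prob") {
    return(probs)
  }
  max.col(probs, ties.method = "first") - 1L
}

#' Accuracy and normalized confusion matrix for predicted labels
#'
#' @param labels True digit labels, 0..9.
#' @param predicted Predicted digit labels, 0..9.
#' @return An `evaluation_result`: list with `accuracy` and `confusion`
#'   (10x10 true-by-predicted matrix, each occupied row normalized to sum
#'   to 1).
#' @export
classification_report <- function(labels, predicted) {
  if (length(labels) == 0L) stop("empty test set")
  stopifnot(length(labels) == length(predicted))
  counts <- table(
    factor(labels, levels = 0:9),
    factor(predicted, levels = 0:9)
  )
  confusion <- unclass(counts / pmax(rowSums(counts), 1L))
  structure(
    list(
      accuracy = mean(labels == predicted),
      confusion = matrix(confusion, 10, 10, dimnames = dimnames(counts)),
      n = length(labels)
    ),
    class = "evaluation_result"
  )
}

#' Evaluate a trained network on a test set
#'
#' @param network A `trained_network`.
#' @param dataset A `colored_digits` test set.
#' @return An `evaluation_result` (see [classification_report()]).
#' @export
evaluate_network <- function(network, dataset) {
  stopifnot(inherits(network, "trained_network"))
  if (length(dataset$labels) == 0L) stop("empty test set")
  pred <- predict(network, dataset, type = "class")
  classification_report(dataset$labels, pred)
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result> accuracy", sprintf("%.4f", x$accuracy), "on", x$n,
    "images\n",
    sep = " "
  )
  invisible(x)
}
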