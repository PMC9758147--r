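#' Extract intermediate convolutional activations
#'
#' Runs the test images through the network and returns the post-ReLU output
#' of one of the three convolutional layers, before the following pooling
#' stage. The three layers produce maps of shape 26x26x32, 11x11x64 and
#' 3x3x64 respectively. Batch order is preserved and results are independent
#' of batch composition.
#'
#' @param network A `trained_network`.
#' @param dataset A `colored_digits` dataset.
#' @param layer_index Convolutional layer to tap: 1, 2 or 3.
#' @return An `activation_tensor`: an `n x h x w x d` array with attribute
#'   `layer_index`.
#' @export
extract_activations <- function(network, dataset, layer_index) {
  stopifnot(inherits(network, "trained_network"), inherits(dataset, "colored_digits"))
  if (!layer_index %in% 1:3) stop("layer_index must be 1, 2 or 3")
  harvest_activations(network, dataset)[[layer_index]]
}

# Single forward pass returning all three activation tensors; shared by
# extract_activations and the pipeline, where tapping each layer separately
# would triple the cost.
harvest_activations <- function(network, dataset) {
  out <- cnn_forward_cpp(dataset$images, network$weights, TRUE)
  shapes <- list(c(26L, 26L, 32L), c(11L, 11L, 64L), c(3L, 3L, 64L))
  lapply(1:3, function(l) {
    sh <- shapes[[l]]
    m <- out[[paste0("A", l)]]
    n <- nrow(m)
    # backend columns are k = (r*w + c) + h*w*f (0-based): c fastest, then
    # r, then filter -> reshape as (n, w, h, d) and swap to (n, h, w, d)
    arr <- array(m, dim = c(n, sh[2], sh[1], sh[3]))
    arr <- aperm(arr, c(1L, 3L, 2L, 4L))
    structure(arr, layer_index = l, class = c("activation_tensor", "array"))
  })
}

#' Flatten an activation tensor to a pixel-level feature matrix
#'
#' Each activation pixel of each filter becomes one feature, giving
#' N = h*w*d columns (21,632 / 7,744 / 576 for layers 1-3). Feature order is
#' row-major over the map then filter: index `((r-1)*w + (c-1))*d + f`,
#' stable across runs; principal-component spectra are invariant to this
#' choice but saved matrices depend on it.
#'
#' @param tensor An `activation_tensor` from [extract_activations()].
#' @return An `n x N` matrix with attributes `layer_scope` and `map_dim`.
#' @export
flatten_pixels <- function(tensor) {
  d <- dim(tensor)
  stopifnot(length(d) == 4L)
  # want feature index f-fastest, then c, then r: permute to (n, d, w, h)
  m <- aperm(unclass(tensor), c(1L, 4L, 3L, 2L))
  dim(m) <- c(d[1], prod(d[2:4]))
  structure(m,
    layer_scope = as.character(attr(tensor, "layer_index")),
    map_dim = d[2:4]
  )
}

#' Invert [flatten_pixels()]
#'
#' @param matrix A matrix produced by [flatten_pixels()] (its `map_dim`
#'   attribute supplies the target shape).
#' @return The original `activation_tensor`.
#' @export
unflatten_pixels <- function(matrix) {
  sh <- attr(matrix, "map_dim")
  stopifnot(!is.null(sh))
  n <- nrow(matrix)
  arr <- array(matrix, dim = c(n, sh[3], sh[2], sh[1]))
  arr <- aperm(arr, c(1L, 4L, 3L, 2L))
  structure(arr,
    layer_index = as.integer(attr(matrix, "layer_scope")),
    class = c("activation_tensor", "array")
  )
}

#' Per-filter mean activations
#'
#' Summarises each filter by the arithmetic mean of its pixel activations,
#' per image, giving M = d columns (32 / 64 / 64 for layers 1-3).
#'
#' @param tensor An `activation_tensor`.
#' @return An `n x d` matrix with attribute `layer_scope`.
#' @export
filter_means <- function(tensor) {
  d <- dim(tensor)
  stopifnot(length(d) == 4L)
  m <- unclass(tensor)
  dim(m) <- c(d[1], d[2] * d[3], d[4])
  out <- apply(m, 3L, rowMeans)
  if (is.null(dim(out))) out <- matrix(out, nrow = d[1])
  structure(out, layer_scope = as.character(attr(tensor, "layer_index")))
}

#' Concatenate per-layer feature matrices into an all-layers matrix
#'
#' Column-binds matrices in layer order, checking that they describe the same
#' samples in the same order. Pixel-level matrices concatenate to 29,952
#' columns, filter-level ones to 160.
#'
#' @param matrices List of feature matrices (from [flatten_pixels()] or
#'   [filter_means()]) in layer order.
#' @return A single matrix with `layer_scope = "all"`.
#' @export
concat_scopes <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  ns <- vapply(matrices, nrow, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("sample-count mismatch across feature matrices: ", paste(ns, collapse = ", "))
  }
  out <- do.call(cbind, lapply(matrices, unclass))
  structure(out, layer_scope = "all")
}
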