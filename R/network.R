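#' Declare a single network layer
#'
#' @param kind One of `"conv"`, `"maxpool"`, `"flatten"`, `"dense"`.
#' @param filters Number of convolutional filters (conv layers).
#' @param units Number of output units (dense layers).
#' @param kernel `(h, w)` kernel size for conv (3x3) or pool window for
#'   maxpool (2x2).
#' @param activation Name of the nonlinearity (`"relu"`, `"softmax"`, or
#'   `NULL` for none).
#' @return A `layer_spec` object.
#' @export
layer_spec <- function(kind = c("conv", "maxpool", "flatten", "dense"),
                       filters = NULL, units = NULL, kernel = NULL,
                       activation = NULL) {
  kind <- match.arg(kind)
  if (kind == "conv") {
    stopifnot(!is.null(filters), !is.null(kernel), length(kernel) == 2L)
  }
  if (kind == "maxpool") stopifnot(!is.null(kernel), length(kernel) == 2L)
  if (kind == "dense") stopifnot(!is.null(units))
  structure(
    list(
      kind = kind, filters = filters, units = units, kernel = kernel,
      activation = activation
    ),
    class = "layer_spec"
  )
}

#' The convolutional architecture under study
#'
#' Three 3x3 valid (unpadded, stride 1) convolutions interleaved with 2x2
#' max-pooling, then a 64-unit dense layer and a 10-way softmax output,
#' operating on 28x28 RGB input. Rectified-linear activations throughout the
#' hidden layers. Per-layer trainable parameter counts are
#' 896 / 18,496 / 36,928 / 36,928 / 650 (94,826 total) and the output shapes
#' run (26,26,32) -> (13,13,32) -> (11,11,64) -> (5,5,64) -> (3,3,64) ->
#' 576 -> 64 -> 10; see [network_summary()].
#'
#' @param input_shape Input image shape, `(h, w, depth)`.
#' @return A `network_spec` object.
#' @export
cnn_spec <- function(input_shape = c(28L, 28L, 3L)) {
  layers <- list(
    layer_spec("conv", filters = 32L, kernel = c(3L, 3L), activation = "relu"),
    layer_spec("maxpool", kernel = c(2L, 2L)),
    layer_spec("conv", filters = 64L, kernel = c(3L, 3L), activation = "relu"),
    layer_spec("maxpool", kernel = c(2L, 2L)),
    layer_spec("conv", filters = 64L, kernel = c(3L, 3L), activation = "relu"),
    layer_spec("flatten"),
    layer_spec("dense", units = 64L, activation = "relu"),
    layer_spec("dense", units = 10L, activation = "softmax")
  )
  structure(
    list(layers = layers, input_shape = as.integer(input_shape)),
    class = "network_spec"
  )
}

#' Trainable parameter count of a layer
#'
#' Convolution: `(kh * kw * input_depth + 1) * filters` (one bias per
#' filter). Dense: `(inputs + 1) * units`. Pooling and flatten layers have no
#' parameters.
#'
#' @param layer A [layer_spec()].
#' @param input_depth Depth of the incoming feature map (conv) or number of
#'   incoming features (dense).
#' @return Integer parameter count.
#' @export
#' @examples
#' count_parameters(layer_spec("conv", filters = 32, kernel = c(3, 3)), 3) # 896
count_parameters <- function(layer, input_depth) {
  stopifnot(inherits(layer, "layer_spec"))
  switch(layer$kind,
    conv = (prod(layer$kernel) * input_depth + 1L) * layer$filters,
    dense = (input_depth + 1L) * layer$units,
    0L
  )
}

#' Output shape of a layer
#'
#' Valid 3x3 convolution maps `(h, w, d)` to `(h - kh + 1, w - kw + 1,
#' filters)`; 2x2 max pooling to `(floor(h/2), floor(w/2), d)` (odd rows or
#' columns are dropped); flatten to the scalar `h * w * d`; dense to its unit
#' count.
#'
#' @param layer A [layer_spec()].
#' @param input_shape `(h, w, d)` for conv/pool/flatten, or a scalar feature
#'   count for dense.
#' @return The output shape: `(h, w, d)` vector or a scalar feature count.
#' @export
output_shape <- function(layer, input_shape) {
  stopifnot(inherits(layer, "layer_spec"))
  switch(layer$kind,
    conv = {
      stopifnot(length(input_shape) == 3L)
      oh <- input_shape[1] - layer$kernel[1] + 1L
      ow <- input_shape[2] - layer$kernel[2] + 1L
      if (oh < 1L || ow < 1L) stop("kernel larger than input feature map")
      c(oh, ow, layer$filters)
    },
    maxpool = {
      stopifnot(length(input_shape) == 3L)
      c(input_shape[1] %/% 2L, input_shape[2] %/% 2L, input_shape[3])
    },
    flatten = prod(input_shape),
    dense = layer$units
  )
}

#' Per-layer accounting for a network specification
#'
#' Walks the layer stack computing each layer's output shape and trainable
#' parameter count analytically.
#'
#' @param spec A [cnn_spec()] network specification.
#' @return A data frame with columns `layer`, `kind`, `output_shape`
#'   (printable string), `params`; total parameters in
#'   `attr(, "total_params")`.
#' @export
network_summary <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  shape <- spec$input_shape
  rows <- lapply(seq_along(spec$layers), function(i) {
    layer <- spec$layers[[i]]
    depth <- if (length(shape) == 3L) shape[3] else shape
    params <- count_parameters(layer, depth)
    shape <<- output_shape(layer, shape)
    data.frame(
      layer = i, kind = layer$kind,
      output_shape = paste(shape, collapse = "x"),
      params = as.integer(params)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "total_params") <- sum(out$params)
  out
}

#' Output shapes of every layer
#'
#' @param spec A [cnn_spec()] network specification.
#' @return A list of shapes, one per layer, in layer order.
#' @export
network_shapes <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  shape <- spec$input_shape
  lapply(spec$layers, function(layer) {
    shape <<- output_shape(layer, shape)
    shape
  })
}

# The compiled training backend implements exactly the canonical stack;
# refuse anything else loudly.
assert_canonical_spec <- function(spec) {
  ref <- cnn_spec()
  if (!identical(
    network_summary(spec)[c("kind", "output_shape", "params")],
    network_summary(ref)[c("kind", "output_shape", "params")]
  ) || !identical(spec$input_shape, ref$input_shape)) {
    stop("the training backend supports only the canonical cnn_spec() stack")
  }
  invisible(spec)
}
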