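#' Parameters for the synthetic digit-glyph generator
#'
#' The generator renders seven-segment-style digit skeletons onto a 28x28
#' ink-on-white canvas and perturbs them with a random affine jitter,
#' Gaussian blur and clipped additive noise, producing greyscale digit images
#' with the statistical structure the downstream analyses assume: geometry
#' carries the class label, classes are separable, and images vary within a
#' class.
#'
#' @param n_per_class Images generated per digit class.
#' @param rotation Maximum rotation jitter, degrees (drawn uniformly in
#'   `[-rotation, rotation]`).
#' @param translation Maximum translation jitter in pixels, per axis.
#' @param scale Maximum relative scale jitter (scale factor drawn uniformly
#'   in `[1 - scale, 1 + scale]`).
#' @param stroke_width Stroke width of the rendered segments, pixels.
#' @param blur_sigma Standard deviation of the Gaussian blur, pixels; 0
#'   disables blurring.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise in
#'   ink-intensity units; values are clamped back to `[0, 1]`. 0 disables.
#' @param seed Integer seed driving the whole dataset build.
#' @return A `glyph_params` object.
#' @export
glyph_params <- function(n_per_class = 100L, rotation = 20, translation = 1.5,
                         scale = 0.12, stroke_width = 2.2, blur_sigma = 0.5,
                         noise_sd = 0.10, seed = 1L) {
  stopifnot(
    n_per_class >= 1, rotation >= 0, translation >= 0, scale >= 0,
    scale < 1, stroke_width > 0, blur_sigma >= 0, noise_sd >= 0
  )
  structure(
    list(
      n_per_class = as.integer(n_per_class), rotation = rotation,
      translation = translation, scale = scale, stroke_width = stroke_width,
      blur_sigma = blur_sigma, noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "glyph_params"
  )
}

# Seven-segment geometry on the 28x28 canvas, coordinates as (row, col).
# Segment endpoints: box rows 5..23, cols 9..19, middle bar at row 14.
segment_coords <- function() {
  list(
    A = c(5, 9, 5, 19), # top
    B = c(5, 19, 14, 19), # top right
    C = c(14, 19, 23, 19), # bottom right
    D = c(23, 9, 23, 19), # bottom
    E = c(14, 9, 23, 9), # bottom left
    F = c(5, 9, 14, 9), # top left
    G = c(14, 9, 14, 19) # middle
  )
}

digit_segments <- function() {
  list(
    `0` = c("A", "B", "C", "D", "E", "F"),
    `1` = c("B", "C"),
    `2` = c("A", "B", "G", "E", "D"),
    `3` = c("A", "B", "G", "C", "D"),
    `4` = c("F", "G", "B", "C"),
    `5` = c("A", "F", "G", "C", "D"),
    `6` = c("A", "F", "G", "E", "D", "C"),
    `7` = c("A", "B", "C"),
    `8` = c("A", "B", "C", "D", "E", "F", "G"),
    `9` = c("A", "B", "C", "D", "F", "G")
  )
}

# Anti-aliased distance rendering of line segments: intensity ramps from 1
# inside the stroke core to 0 one pixel outside it.
rasterize_segments <- function(segs, stroke_width, h = 28L, w = 28L) {
  rows <- matrix(rep(seq_len(h), w), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  img <- matrix(0, h, w)
  half <- stroke_width / 2
  aa <- 1 # anti-alias falloff width, pixels
  for (s in segs) {
    p1 <- s[1:2]
    p2 <- s[3:4]
    v <- p2 - p1
    len2 <- sum(v^2)
    # projection parameter of each pixel center onto the segment, clamped
    t <- if (len2 == 0) {
      matrix(0, h, w)
    } else {
      pmin(1, pmax(0, ((rows - p1[1]) * v[1] + (cols - p1[2]) * v[2]) / len2))
    }
    d <- sqrt((rows - (p1[1] + t * v[1]))^2 + (cols - (p1[2] + t * v[2]))^2)
    g <- pmin(1, pmax(0, (half + aa - d) / aa))
    img <- pmax(img, g)
  }
  img
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) {
    return(img)
  }
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(img)
  w <- ncol(img)
  pad <- matrix(0, h + 2 * r, w + 2 * r)
  pad[r + seq_len(h), r + seq_len(w)] <- img
  # separable convolution, zero padding (background carries no ink)
  tmp <- apply(pad, 2, function(col) stats::filter(col, k, sides = 2))
  tmp[is.na(tmp)] <- 0
  out <- t(apply(tmp, 1, function(row) {
    x <- stats::filter(row, k, sides = 2)
    x[is.na(x)] <- 0
    x
  }))
  out[r + seq_len(h), r + seq_len(w)]
}

#' Generate one synthetic digit glyph
#'
#' Renders the seven-segment skeleton of `digit`, jittered by a random affine
#' transform of the segment endpoints (rotation, translation, isotropic scale
#' about the canvas center), then blurred and noised per `params`. Uses the
#' current RNG stream; wrap in a seeded context (or use
#' [generate_glyph_dataset()]) for reproducibility.
#'
#' @param digit Integer in 0..9.
#' @param params A [glyph_params()] object.
#' @return A list with `pixels` (28x28 ink-intensity matrix in `[0, 1]`) and
#'   `label`.
#' @export
generate_glyph <- function(digit, params = glyph_params()) {
  digit <- as.integer(digit)
  if (digit < 0L || digit > 9L) stop("digit must be in 0..9")
  segs <- segment_coords()[digit_segments()[[as.character(digit)]]]

  theta <- runif(1, -params$rotation, params$rotation) * pi / 180
  s <- runif(1, 1 - params$scale, 1 + params$scale)
  dtr <- runif(2, -params$translation, params$translation)
  ctr <- c(14, 14)
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  xf <- function(p) as.numeric(s * rot %*% (p - ctr) + ctr + dtr)
  segs <- lapply(segs, function(sg) c(xf(sg[1:2]), xf(sg[3:4])))

  img <- rasterize_segments(segs, params$stroke_width)
  img <- gaussian_blur(img, params$blur_sigma)
  if (params$noise_sd > 0) {
    img <- img + matrix(rnorm(length(img), 0, params$noise_sd), nrow(img))
  }
  img <- matrix(pmin(1, pmax(0, img)), 28L, 28L)
  list(pixels = img, label = digit)
}

#' Generate a class-balanced synthetic digit dataset
#'
#' Produces `n_per_class` glyphs for each digit 0..9 and shuffles them
#' deterministically. The entire build (jitter draws, noise, shuffle) is a
#' function of `params$seed` alone.
#'
#' @param params A [glyph_params()] object.
#' @return A `grey_digits` object (same contract as [load_mnist_idx()]).
#' @export
#' @examples
#' ds <- generate_glyph_dataset(glyph_params(n_per_class = 2, seed = 42))
#' table(ds$labels)
generate_glyph_dataset <- function(params = glyph_params()) {
  stopifnot(inherits(params, "glyph_params"))
  n <- params$n_per_class * 10L
  with_seed(params$seed, {
    images <- array(0, dim = c(n, 28L, 28L))
    labels <- integer(n)
    i <- 0L
    for (digit in 0:9) {
      for (k in seq_len(params$n_per_class)) {
        i <- i + 1L
        gl <- generate_glyph(digit, params)
        images[i, , ] <- gl$pixels
        labels[i] <- gl$label
      }
    }
    ord <- sample.int(n)
    structure(
      list(images = images[ord, , , drop = FALSE], labels = labels[ord]),
      class = "grey_digits"
    )
  })
}

#' Nearest-class-centroid baseline classifier
#'
#' Trivial raw-pixel baseline used to certify that glyph classes are
#' geometrically separable: each class is summarised by its mean training
#' image and test images are assigned to the nearest centroid in Euclidean
#' pixel space.
#'
#' @param train,test `grey_digits` datasets.
#' @return Classification accuracy on `test`, a fraction in `[0, 1]`.
#' @export
nearest_centroid_accuracy <- function(train, test) {
  stopifnot(inherits(train, "grey_digits"), inherits(test, "grey_digits"))
  xtr <- matrix(train$images, dim(train$images)[1])
  xte <- matrix(test$images, dim(test$images)[1])
  classes <- sort(unique(train$labels))
  centroids <- t(vapply(
    classes,
    function(cl) colMeans(xtr[train$labels == cl, , drop = FALSE]),
    numeric(ncol(xtr))
  ))
  # squared distances via the expansion ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2
  d2 <- -2 * xte %*% t(centroids)
  d2 <- sweep(d2, 2, rowSums(centroids^2), "+")
  pred <- classes[max.col(-d2, ties.method = "first")]
  mean(pred == test$labels)
}
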