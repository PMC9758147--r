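#' Read a digit dataset stored in IDX format
#'
#' Reads the standard big-endian IDX pair used by the MNIST handwritten-digit
#' database: an image file with magic number 2051 (`0x00000803`, unsigned
#' bytes, 3 dimensions) and a label file with magic number 2049
#' (`0x00000801`). Raw byte values are scaled to `[0, 1]` and interpreted as
#' ink intensity (1 = full ink, 0 = background), which renders as dark digits
#' on a white background once passed through [colorize()]; this matches the
#' stroke-on-white presentation the downstream pipeline assumes.
#'
#' @param images_path Path to the IDX image file (e.g.
#'   `train-images-idx3-ubyte`).
#' @param labels_path Path to the matching IDX label file.
#' @return A `grey_digits` object: list with `images` (`n x 28 x 28` array of
#'   ink intensities) and `labels` (integer vector in 0..9).
#' @export
load_mnist_idx <- function(images_path, labels_path) {
  if (!file.exists(images_path)) stop("image file not found: ", images_path)
  if (!file.exists(labels_path)) stop("label file not found: ", labels_path)

  icon <- file(images_path, "rb")
  on.exit(close(icon), add = TRUE)
  magic <- readBin(icon, "integer", 1L, size = 4L, endian = "big")
  if (!identical(magic, 2051L)) {
    stop("malformed image file: expected IDX magic 2051, got ", magic)
  }
  n <- readBin(icon, "integer", 1L, size = 4L, endian = "big")
  h <- readBin(icon, "integer", 1L, size = 4L, endian = "big")
  w <- readBin(icon, "integer", 1L, size = 4L, endian = "big")
  payload <- readBin(icon, "raw", n * h * w)
  if (length(payload) < n * h * w) {
    stop(
      "image payload truncated: expected ", n * h * w, " bytes, found ",
      length(payload)
    )
  }

  lcon <- file(labels_path, "rb")
  on.exit(close(lcon), add = TRUE)
  lmagic <- readBin(lcon, "integer", 1L, size = 4L, endian = "big")
  if (!identical(lmagic, 2049L)) {
    stop("malformed label file: expected IDX magic 2049, got ", lmagic)
  }
  nl <- readBin(lcon, "integer", 1L, size = 4L, endian = "big")
  if (!identical(nl, n)) {
    stop("image/label count mismatch: ", n, " images vs ", nl, " labels")
  }
  labels <- as.integer(readBin(lcon, "raw", nl))
  if (length(labels) < nl) stop("label payload truncated")

  # IDX stores pixels row by row within each image; build (n, h, w) so that
  # images[i, r, c] is row r, column c of image i
  vals <- as.integer(payload) / 255
  images <- aperm(array(vals, dim = c(w, h, n)), c(3L, 2L, 1L))
  structure(list(images = images, labels = labels), class = "grey_digits")
}

#' @export
print.grey_digits <- function(x, ...) {
  d <- dim(x$images)
  cat("<grey_digits>", d[1], "images of", d[2], "x", d[3], "\n")
  invisible(x)
}
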