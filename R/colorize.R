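#' Six-color palette used for digit colorization
#'
#' The three primary colors of the RGB model and their complementary
#' counterparts, each channel saturated (0 or 1).
#'
#' @return A data frame with columns `name`, `r`, `g`, `b`; one row per color
#'   in the fixed order red, green, blue, cyan, magenta, yellow.
#' @export
#' @examples
#' color_palette()
color_palette <- function() {
  data.frame(
    name = c("red", "green", "blue", "cyan", "magenta", "yellow"),
    r = c(1, 0, 0, 0, 1, 1),
    g = c(0, 1, 0, 1, 0, 1),
    b = c(0, 0, 1, 1, 1, 0),
    stringsAsFactors = FALSE
  )
}

#' Fixed digit-to-color map for the low-dimensional training regime
#'
#' Pairs consecutive digits with a single color: red for 0 and 1, cyan for
#' 2 and 3, green for 4 and 5, magenta for 6 and 7, yellow for 8 and 9.
#' Blue is never assigned under this map.
#'
#' @return An integer vector of length 10, named `"0"` to `"9"`, whose values
#'   index rows of [color_palette()].
#' @export
fixed_color_map <- function() {
  pal <- color_palette()
  idx <- function(nm) match(nm, pal$name)
  map <- c(
    idx("red"), idx("red"),
    idx("cyan"), idx("cyan"),
    idx("green"), idx("green"),
    idx("magenta"), idx("magenta"),
    idx("yellow"), idx("yellow")
  )
  names(map) <- as.character(0:9)
  map
}

#' Describe a color-assignment rule
#'
#' @param mode `"RC"` for random color assignment (color drawn uniformly from
#'   the six palette entries, independently of the digit) or `"FC"` for fixed
#'   color assignment (color determined by the digit via `fixed_map`).
#' @param fixed_map Digit-to-palette-index map used in FC mode; defaults to
#'   [fixed_color_map()].
#' @return An object of class `color_assignment`.
#' @export
color_assignment <- function(mode = c("RC", "FC"), fixed_map = fixed_color_map()) {
  mode <- match.arg(mode)
  if (mode == "FC") {
    stopifnot(length(fixed_map) == 10L)
    if (!all(fixed_map %in% seq_len(nrow(color_palette())))) {
      stop("fixed_map entries must index the 6-color palette")
    }
  }
  structure(list(mode = mode, fixed_map = fixed_map), class = "color_assignment")
}

#' @export
print.color_assignment <- function(x, ...) {
  cat("<color_assignment> mode:", x$mode, "\n")
  if (x$mode == "FC") {
    pal <- color_palette()
    cat("  map:", paste0(names(x$fixed_map), "->", pal$name[x$fixed_map],
      collapse = " "
    ), "\n")
  }
  invisible(x)
}

#' Colorize a greyscale digit image
#'
#' Blends each pixel linearly between the white background and the assigned
#' color according to its ink intensity `g`:
#' `channel = (1 - g) * 1 + g * color_channel`. Background pixels (`g = 0`)
#' stay white; full-ink pixels take the pure color; intermediate grey levels
#' become saturation levels of the color. The set of pixels carrying ink is
#' unchanged by construction.
#'
#' @param pixels A 28x28 (or any h x w) matrix of ink intensities in `[0, 1]`,
#'   1 meaning full ink.
#' @param color A length-3 RGB triple in `[0, 1]`, normally a palette row.
#' @return An h x w x 3 array with values in `[0, 1]`.
#' @export
#' @examples
#' img <- matrix(0, 28, 28)
#' img[10:18, 14] <- 1
#' rgb <- colorize(img, c(1, 0, 0)) # a red stroke on white
colorize <- function(pixels, color) {
  stopifnot(is.matrix(pixels), length(color) == 3L)
  if (any(pixels < 0 | pixels > 1)) stop("ink intensities must lie in [0, 1]")
  out <- array(0, dim = c(dim(pixels), 3L))
  for (ch in 1:3) {
    out[, , ch] <- (1 - pixels) + pixels * color[ch]
  }
  out
}

#' Assign a color to one digit image
#'
#' In RC mode the color is drawn uniformly from the six palette entries using
#' the current RNG stream; in FC mode it is looked up from the assignment's
#' fixed map. Pixel colorization is delegated to [colorize()].
#'
#' @param pixels Greyscale ink-intensity matrix (see [colorize()]).
#' @param label Integer digit class in 0..9.
#' @param assignment A [color_assignment()].
#' @return A list with elements `pixels` (h x w x 3 array), `label`, and
#'   `color_id` (palette row index).
#' @export
assign_color <- function(pixels, label, assignment) {
  stopifnot(inherits(assignment, "color_assignment"))
  label <- as.integer(label)
  if (label < 0L || label > 9L) stop("label must be a digit in 0..9")
  pal <- color_palette()
  color_id <- if (assignment$mode == "RC") {
    sample.int(nrow(pal), 1L)
  } else {
    unname(assignment$fixed_map[[as.character(label)]])
  }
  list(
    pixels = colorize(pixels, as.numeric(pal[color_id, c("r", "g", "b")])),
    label = label,
    color_id = color_id
  )
}

#' Build a colorized dataset from greyscale digits
#'
#' Applies a color-assignment rule to every image of a greyscale digit
#' dataset. The build is deterministic given `seed`: RC color draws come from
#' one RNG stream seeded here, so the same seed reproduces the dataset
#' byte for byte, and image order is preserved.
#'
#' @param greyscale A `grey_digits` dataset (from [generate_glyph_dataset()]
#'   or [load_mnist_idx()]), i.e. a list with an `n x 28 x 28` `images` array
#'   and an integer `labels` vector.
#' @param assignment A [color_assignment()].
#' @param seed Integer seed for the RC color stream (ignored in FC mode but
#'   still recorded).
#' @return A `colored_digits` object: list with `images` (`n x 28 x 28 x 3`),
#'   `labels`, `color_id`, `assignment`, `seed`.
#' @export
build_colored_dataset <- function(greyscale, assignment, seed = 1L) {
  stopifnot(inherits(greyscale, "grey_digits"), inherits(assignment, "color_assignment"))
  n <- length(greyscale$labels)
  pal <- color_palette()
  color_id <- if (assignment$mode == "RC") {
    with_seed(seed, sample.int(nrow(pal), n, replace = TRUE))
  } else {
    unname(assignment$fixed_map[as.character(greyscale$labels)])
  }
  h <- dim(greyscale$images)[2]
  w <- dim(greyscale$images)[3]
  images <- array(0, dim = c(n, h, w, 3L))
  for (ch in 1:3) {
    g <- greyscale$images
    images[, , , ch] <- (1 - g) + g * pal[[c("r", "g", "b")[ch]]][color_id]
  }
  structure(
    list(
      images = images, labels = greyscale$labels, color_id = color_id,
      assignment = assignment, seed = seed
    ),
    class = "colored_digits"
  )
}

#' @export
print.colored_digits <- function(x, ...) {
  cat(
    "<colored_digits>", length(x$labels), "images,", x$assignment$mode,
    "assignment\n"
  )
  invisible(x)
}

#' Dataset manifest
#'
#' One row per image: index, digit label and palette color index. Suitable
#' for writing as CSV provenance next to saved datasets.
#'
#' @param dataset A `colored_digits` object.
#' @return A data frame with columns `index`, `label`, `color_id`.
#' @export
dataset_manifest <- function(dataset) {
  stopifnot(inherits(dataset, "colored_digits"))
  data.frame(
    index = seq_along(dataset$labels),
    label = dataset$labels,
    color_id = dataset$color_id
  )
}

#' Write one colored digit as PNG (inspection aid)
#'
#' @param dataset A `colored_digits` object.
#' @param index Image index.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_digit_png <- function(dataset, index, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write PNG files")
  }
  img <- dataset$images[index, , , , drop = TRUE]
  png::writePNG(img, path)
  invisible(path)
}
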