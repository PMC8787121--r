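#' Image plane: a 2-D grid of luminance values
#'
#' The unit every map in the package is computed on: a numeric matrix of
#' finite pixel values in `[0, dynamic_range]`. Rows index image rows
#' (top to bottom), columns index image columns (left to right); all
#' documented pixel positions use the 0-based `(row, col)` convention
#' even though R matrices are 1-indexed internally.
#'
#' @param pixels numeric matrix of luminance values.
#' @param dynamic_range positive scalar, the nominal maximum pixel value
#'   (255 for 8-bit imagery).
#' @return An object of class `image_plane`: the pixel matrix with a
#'   `dynamic_range` attribute.
#' @examples
#' img <- image_plane(matrix(0:254, nrow = 15))
#' dim(img)
#' @export
image_plane <- function(pixels, dynamic_range = 255) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 3L || ncol(pixels) < 3L) {
    stop("image must be at least 3x3 (gradient masks must fit)", call. = FALSE)
  }
  if (!is.numeric(dynamic_range) || length(dynamic_range) != 1L ||
      !is.finite(dynamic_range) || dynamic_range <= 0) {
    stop("`dynamic_range` must be a positive finite scalar", call. = FALSE)
  }
  if (anyNA(pixels) || !all(is.finite(pixels))) {
    stop("pixel values must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > dynamic_range) {
    stop(sprintf("pixel values must lie in [0, %g]", dynamic_range),
         call. = FALSE)
  }
  structure(unclass(pixels), dynamic_range = dynamic_range,
            class = c("image_plane", "matrix", "array"))
}

#' Coerce to an image plane
#'
#' @param x matrix or `image_plane`.
#' @param dynamic_range used when `x` carries no range attribute.
#' @return an `image_plane`.
#' @export
as_image_plane <- function(x, dynamic_range = 255) {
  if (inherits(x, "image_plane")) return(x)
  image_plane(as.matrix(x), dynamic_range = dynamic_range)
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %d x %d, dynamic range %g, pixel range [%g, %g]\n",
              nrow(x), ncol(x), attr(x, "dynamic_range"),
              min(x), max(x)))
  invisible(x)
}

#' Dynamic range of an image plane
#' @param x an `image_plane`.
#' @return positive scalar.
#' @export
dynamic_range <- function(x) {
  dr <- attr(x, "dynamic_range")
  if (is.null(dr)) 255 else dr
}

## strip class/attributes down to a plain numeric matrix
as_plain_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "dynamic_range") <- NULL
  class(m) <- NULL
  dim(m) <- dim(x)
  m
}

check_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must share dimensions (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}
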