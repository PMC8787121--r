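#' Pixelwise similarity transform
#'
#' The shared functional form behind every comparison map in the
#' metric — contour, luminance, contrast and gradient similarity:
#' `s(a, b) = (2ab + C) / (a^2 + b^2 + C)` evaluated per pixel. For
#' nonnegative operands the value lies in `(0, 1]`, equals 1 exactly
#' where the operands agree, and decreases as they diverge; the
#' stabiliser `C` keeps the ratio well-defined when both operands
#' approach zero.
#'
#' @param a,b nonnegative numeric matrices of equal size.
#' @param C positive stabilising constant.
#' @return a `similarity_map`: numeric matrix with attribute
#'   `stabilizer = C`. Symmetric in `(a, b)`.
#' @examples
#' similarity_map(matrix(0.5), matrix(0.25), C = 0.01)  # 0.80620...
#' @export
similarity_map <- function(a, b, C) {
  a <- as_plain_matrix(as.matrix(a))
  b <- as_plain_matrix(as.matrix(b))
  check_same_dim(a, b, "similarity operands")
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0) {
    stop("stabiliser C must be a positive finite scalar", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b) || !all(is.finite(a)) || !all(is.finite(b))) {
    stop("similarity operands must be finite", call. = FALSE)
  }
  if (min(a) < 0 || min(b) < 0) {
    stop("similarity operands must be nonnegative", call. = FALSE)
  }
  s <- (2 * a * b + C) / (a^2 + b^2 + C)
  structure(s, stabilizer = C, class = c("similarity_map", "matrix", "array"))
}

#' Local window specification
#'
#' The locality used for luminance and contrast statistics. The
#' per-pixel mean and standard deviation need a neighbourhood; the
#' default is the SSIM convention (11 x 11 Gaussian, sigma 1.5,
#' symmetric border padding). A `box` window gives unweighted local
#' statistics, and `global` degenerates to one mean/sd for the whole
#' image (the literal whole-image reading of the average-intensity and
#' standard-deviation formulas).
#'
#' @param kind `"gaussian"`, `"box"` or `"global"`.
#' @param size odd window size in pixels (ignored for `global`).
#' @param sigma Gaussian scale (gaussian windows only).
#' @return a `window_spec` list; weights always sum to 1.
#' @export
window_spec <- function(kind = c("gaussian", "box", "global"), size = 11L,
                        sigma = 1.5) {
  kind <- match.arg(kind)
  if (kind != "global") {
    if (size < 1 || size %% 2 == 0) {
      stop("window size must be an odd positive integer", call. = FALSE)
    }
  }
  if (kind == "gaussian" && sigma <= 0) {
    stop("sigma must be positive", call. = FALSE)
  }
  structure(list(kind = kind, size = as.integer(size), sigma = sigma,
                 padding = "symmetric"),
            class = "window_spec")
}

window_taps <- function(window) {
  if (window$kind == "box") {
    box_taps(window$size)
  } else {
    x <- seq_len(window$size) - (window$size + 1L) / 2
    w <- exp(-(x^2) / (2 * window$sigma^2))
    w / sum(w)
  }
}

#' Local (or global) mean map
#'
#' Weighted average intensity under the window at every pixel,
#' symmetric padding at the borders; with a `global` window, a constant
#' map holding the whole-image mean.
#'
#' @param image an [image_plane()] or numeric matrix.
#' @param window a [window_spec()].
#' @return numeric matrix, same size as the input.
#' @export
local_mean_map <- function(image, window = window_spec()) {
  m <- as_plain_matrix(as.matrix(image))
  if (window$kind == "global") {
    return(matrix(mean(m), nrow(m), ncol(m)))
  }
  filter_separable(m, window_taps(window))
}

#' Local (or global) standard-deviation map
#'
#' Square root of the locally weighted second central moment. For the
#' unweighted `box` window (and the `global` mode) the small-sample
#' `N/(N-1)` correction is applied, matching the sample standard
#' deviation; the Gaussian window uses the plain weighted moment (the
#' SSIM convention).
#'
#' @inheritParams local_mean_map
#' @return nonnegative numeric matrix, same size as the input.
#' @export
local_std_map <- function(image, window = window_spec()) {
  m <- as_plain_matrix(as.matrix(image))
  if (window$kind == "global") {
    n <- length(m)
    v <- sum((m - mean(m))^2) / max(1, n - 1)
    return(matrix(sqrt(v), nrow(m), ncol(m)))
  }
  taps <- window_taps(window)
  mu <- filter_separable(m, taps)
  m2 <- filter_separable(m * m, taps) - mu^2
  if (window$kind == "box") {
    n <- window$size^2
    m2 <- m2 * n / (n - 1)
  }
  m2[m2 < 0] <- 0  # fp guard
  sqrt(m2)
}

## Scharr 3/10/3 derivative masks with the 1/16 normalisation;
## correlation (not flipped) orientation, documented on the magnitudes
scharr_h <- matrix(c(3, 0, -3, 10, 0, -10, 3, 0, -3) / 16, 3, 3, byrow = TRUE)
scharr_v <- t(scharr_h)

#' Scharr gradient-magnitude map
#'
#' `s = sqrt((S_h * x)^2 + (S_v * x)^2)` with the normalised Scharr
#' masks `S_h = [[3,0,-3],[10,0,-10],[3,0,-3]]/16` and `S_v` its
#' transpose, applied as correlations with symmetric border padding.
#' The magnitude is invariant to adding a constant to the image and
#' rotates with the image under 90-degree rotation.
#'
#' @param image an [image_plane()] or numeric matrix, at least 3 x 3.
#' @return nonnegative numeric matrix, same size as the input.
#' @export
scharr_gradient_magnitude <- function(image) {
  m <- as_plain_matrix(as.matrix(image))
  if (nrow(m) < 3 || ncol(m) < 3) {
    stop("image must be at least 3x3 for the Scharr masks", call. = FALSE)
  }
  gh <- filter_separable(m, c(3, 10, 3) / 16, c(1, 0, -1))
  gv <- filter_separable(m, c(1, 0, -1), c(3, 10, 3) / 16)
  sqrt(gh^2 + gv^2)
}
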