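## Low-level grid numerics: symmetric padding, separable filtering,
## Gaussian/box kernels, bilinear resampling. All operate on plain
## numeric matrices and are deterministic.

## symmetric ("reflect including edge") index vector of length n + 2*pad
symmetric_indices <- function(n, pad) {
  if (pad == 0L) return(seq_len(n))
  if (pad > n) stop("padding exceeds image extent", call. = FALSE)
  c(rev(seq_len(pad)), seq_len(n), n - seq_len(pad) + 1L)
}

pad_symmetric <- function(m, pad_r, pad_c = pad_r) {
  m[symmetric_indices(nrow(m), pad_r), symmetric_indices(ncol(m), pad_c),
    drop = FALSE]
}

## separable correlation with 1-D taps along rows then columns,
## symmetric border padding; output has the input's dimensions
filter_separable <- function(m, taps_row, taps_col = taps_row) {
  kr <- length(taps_row)
  kc <- length(taps_col)
  if (kr %% 2L == 0L || kc %% 2L == 0L) {
    stop("kernel lengths must be odd", call. = FALSE)
  }
  hr <- (kr - 1L) %/% 2L
  hc <- (kc - 1L) %/% 2L
  if (hr > nrow(m) || hc > ncol(m)) {
    stop("window larger than 2x image extent", call. = FALSE)
  }
  p <- pad_symmetric(m, hr, hc)
  nr <- nrow(m); nc <- ncol(m)
  ## vertical pass (down rows)
  v <- matrix(0, nr, ncol(p))
  for (i in seq_len(kr)) {
    v <- v + taps_row[i] * p[i:(i + nr - 1L), , drop = FALSE]
  }
  ## horizontal pass (across columns)
  out <- matrix(0, nr, nc)
  for (j in seq_len(kc)) {
    out <- out + taps_col[j] * v[, j:(j + nc - 1L), drop = FALSE]
  }
  out
}

## general (non-separable) 3x3 correlation, symmetric padding
filter_3x3 <- function(m, mask) {
  stopifnot(identical(dim(mask), c(3L, 3L)))
  p <- pad_symmetric(m, 1L, 1L)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in 1:3) for (j in 1:3) {
    if (mask[i, j] != 0) {
      out <- out + mask[i, j] * p[i:(i + nr - 1L), j:(j + nc - 1L)]
    }
  }
  out
}

box_taps <- function(k) rep(1 / k, k)

## Gaussian taps truncated at `truncate` sigmas, normalised to sum 1
gaussian_taps <- function(sigma, truncate = 4) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  half <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- (-half):half
  w <- exp(-(x^2) / (2 * sigma^2))
  w / sum(w)
}

gaussian_smooth <- function(m, sigma, truncate = 4) {
  t1 <- gaussian_taps(sigma, truncate)
  half <- (length(t1) - 1L) %/% 2L
  ## clamp the kernel so it never exceeds what symmetric padding allows
  maxh <- min(nrow(m), ncol(m))
  if (half > maxh) {
    t1 <- t1[(half - maxh + 1L):(length(t1) - (half - maxh))]
    t1 <- t1 / sum(t1)
  }
  filter_separable(m, t1)
}

box_filter <- function(m, k) {
  filter_separable(m, box_taps(k))
}

## bilinear resampling to (out_h, out_w); pixel centres aligned via the
## half-pixel convention, edge-clamped
resize_bilinear <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  if (out_h == in_h && out_w == in_w) return(m)
  sy <- in_h / out_h
  sx <- in_w / out_w
  yy <- (seq_len(out_h) - 0.5) * sy - 0.5
  xx <- (seq_len(out_w) - 0.5) * sx - 0.5
  y0 <- pmin(pmax(floor(yy), 0), in_h - 1)
  x0 <- pmin(pmax(floor(xx), 0), in_w - 1)
  y1 <- pmin(y0 + 1, in_h - 1)
  x1 <- pmin(x0 + 1, in_w - 1)
  fy <- pmin(pmax(yy - y0, 0), 1)
  fx <- pmin(pmax(xx - x0, 0), 1)
  a <- m[y0 + 1, x0 + 1, drop = FALSE]
  b <- m[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- m[y1 + 1, x0 + 1, drop = FALSE]
  d <- m[y1 + 1, x1 + 1, drop = FALSE]
  wfy <- matrix(fy, out_h, out_w)
  wfx <- matrix(fx, out_h, out_w, byrow = TRUE)
  top <- a * (1 - wfx) + b * wfx
  bot <- c_ * (1 - wfx) + d * wfx
  top * (1 - wfy) + bot * wfy
}

## bilinear lookup of matrix m at fractional (row, col) positions
## (0-based), edge-clamped; rows/cols are equal-length vectors or
## matrices of the output shape
sample_bilinear <- function(m, rows, cols) {
  in_h <- nrow(m); in_w <- ncol(m)
  r <- pmin(pmax(rows, 0), in_h - 1)
  c_ <- pmin(pmax(cols, 0), in_w - 1)
  r0 <- floor(r); c0 <- floor(c_)
  r1 <- pmin(r0 + 1, in_h - 1)
  c1 <- pmin(c0 + 1, in_w - 1)
  fr <- r - r0; fc <- c_ - c0
  idx <- function(ri, ci) m[cbind(as.vector(ri) + 1, as.vector(ci) + 1)]
  out <- idx(r0, c0) * (1 - fr) * (1 - fc) +
    idx(r0, c1) * (1 - fr) * fc +
    idx(r1, c0) * fr * (1 - fc) +
    idx(r1, c1) * fr * fc
  if (is.matrix(rows)) dim(out) <- dim(rows)
  out
}

## round-half-up, the convention used for 8-bit quantisation
round_half_up <- function(x) floor(x + 0.5)
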