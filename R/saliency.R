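#' Parameters of the spectral-residual saliency stage
#'
#' The "main target" extractor: the image is taken to a small working
#' scale, its log-amplitude spectrum is compared against a local (box)
#' average, and the inverse transform of the residual highlights
#' unexpected — salient — structure (pool walls, lane ropes, swimmers).
#'
#' @param working_width image is resized (bilinear, aspect preserved) so
#'   its width equals this before the FFT; the classic spectral-residual
#'   construction works at small scales. Capped at the native width.
#' @param gamma amplitude-stretch exponent; 1 leaves the log-amplitude
#'   spectrum untouched (the published baseline). For `gamma != 1` the
#'   stretch is applied to the spectrum shifted to be nonnegative, then
#'   total energy is restored by the normalisation `(sum A / sum A')`.
#' @param residual_filter_size odd size of the box filter whose output
#'   is subtracted from the log-amplitude spectrum (default 7).
#' @param smooth_sigma Gaussian smoothing scale (working-grid pixels)
#'   applied to the squared inverse transform; kernel truncated at 4
#'   sigma.
#' @param log_epsilon additive guard inside the logarithm so constant
#'   images stay finite.
#' @param stretch_on `"log"` stretches the (shifted) log-amplitude
#'   spectrum; `"amplitude"` stretches the raw amplitude before taking
#'   the log. Identical at `gamma = 1`.
#' @return a `saliency_params` list.
#' @export
saliency_params <- function(working_width = 256L, gamma = 1,
                            residual_filter_size = 7L, smooth_sigma = 3,
                            log_epsilon = 1e-8,
                            stretch_on = c("log", "amplitude")) {
  stretch_on <- match.arg(stretch_on)
  if (working_width < 1) stop("working_width must be positive", call. = FALSE)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (residual_filter_size < 1 || residual_filter_size %% 2 == 0) {
    stop("residual_filter_size must be an odd positive integer", call. = FALSE)
  }
  if (smooth_sigma <= 0) stop("smooth_sigma must be positive", call. = FALSE)
  if (log_epsilon <= 0) stop("log_epsilon must be positive", call. = FALSE)
  structure(list(working_width = as.integer(working_width), gamma = gamma,
                 residual_filter_size = as.integer(residual_filter_size),
                 smooth_sigma = smooth_sigma, log_epsilon = log_epsilon,
                 stretch_on = stretch_on),
            class = "saliency_params")
}

## working-grid size for an image under `params` (aspect preserved)
saliency_working_dim <- function(h, w, params) {
  ww <- min(params$working_width, w)
  wh <- max(3L, as.integer(round(h * ww / w)))
  c(wh, ww)
}

## spectral-residual map on the working grid, raw (pre-normalisation).
## `dft` / `idft` are pluggable only so an independent transform can be
## swapped in by validation code; defaults are the FFT.
spectral_residual_raw <- function(m, params,
                                  dft = function(z) stats::fft(z),
                                  idft = function(z)
                                    stats::fft(z, inverse = TRUE) / length(z)) {
  f <- dft(m)
  amp <- Mod(f)
  phase <- Arg(f)
  if (params$stretch_on == "amplitude" && params$gamma != 1) {
    a_log <- log(amp^params$gamma + params$log_epsilon)
    a_ref <- log(amp + params$log_epsilon)
    s_ref <- sum(a_ref)
    s_new <- sum(a_log)
    a_bar <- if (abs(s_new) > 0) (s_ref / s_new) * a_log else a_log
  } else {
    a <- log(amp + params$log_epsilon)
    if (params$gamma != 1) {
      shifted <- a - min(a)
      a_str <- shifted^params$gamma
      s_ref <- sum(a)
      s_new <- sum(a_str)
      a_bar <- if (abs(s_new) > 0) (s_ref / s_new) * a_str else a
    } else {
      a_bar <- a
    }
  }
  resid <- a_bar - box_filter(a_bar, params$residual_filter_size)
  sal <- Mod(idft(exp(resid + 1i * phase)))^2
  gaussian_smooth(sal, params$smooth_sigma)
}

#' Spectral-residual saliency map
#'
#' Pipeline: resize to the working width (bilinear); 2-D DFT; take the
#' log-amplitude spectrum `A = log(|F| + eps)` and phase; optional
#' amplitude stretch (see [saliency_params()]); residual `R = A -
#' box(A)`; map `|IDFT(exp(R + i phase))|^2`; Gaussian smoothing;
#' resize back to native resolution; max-normalise to `[0, 1]`.
#' Deterministic. Rows/columns follow the 0-based `(row, col)`
#' convention of [image_plane()].
#'
#' @param image an [image_plane()].
#' @param params a [saliency_params()].
#' @return a numeric matrix in `[0, 1]` at the image's native size, of
#'   class `saliency_map`. The maximum is exactly 1 unless the map is
#'   identically 0.
#' @export
spectral_residual_saliency <- function(image, params = saliency_params()) {
  image <- as_image_plane(image)
  m <- as_plain_matrix(image)
  wd <- saliency_working_dim(nrow(m), ncol(m), params)
  mw <- resize_bilinear(m, wd[1], wd[2])
  sal <- spectral_residual_raw(mw, params)
  sal <- resize_bilinear(sal, nrow(m), ncol(m))
  normalize_saliency(sal)
}

normalize_saliency <- function(sal) {
  sal[sal < 0] <- 0  # guard fp dust from the resampler
  mx <- max(sal)
  if (mx > 0) sal <- sal / mx
  structure(sal, class = c("saliency_map", "matrix", "array"))
}

#' Positional weight map for saliency-weighted pooling
#'
#' Each of the two saliency maps is Gaussian-smoothed, then they are
#' combined pixelwise by their union — the fuzzy-set union, i.e. the
#' pixelwise maximum — giving the weight every pooled similarity value
#' receives. Attention drawn by structure in *either* the reference or
#' the distorted image counts.
#'
#' @param sal_ref,sal_dist saliency maps (matrices) of equal size.
#' @param smooth_sigma Gaussian scale of the position smoothing.
#' @return a nonnegative matrix of the shared size.
#' @export
positional_weight_map <- function(sal_ref, sal_dist, smooth_sigma = 3) {
  check_same_dim(sal_ref, sal_dist, "saliency maps")
  if (smooth_sigma <= 0) stop("smooth_sigma must be positive", call. = FALSE)
  a <- gaussian_smooth(as_plain_matrix(sal_ref), smooth_sigma)
  b <- gaussian_smooth(as_plain_matrix(sal_dist), smooth_sigma)
  pmax(a, b)
}
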