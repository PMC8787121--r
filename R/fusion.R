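#' MM-IQA parameter set
#'
#' Every free constant of the metric. Stabilisers follow the
#' conventions of the similarity-map family: `C1 = 1e-4` for maps on
#' `[0, 1]` (saliency), `C2 = (0.01 * 255)^2` for luminance and
#' `C3 = (0.03 * 255)^2` for contrast (the SSIM constants), `C4 = 170`
#' for gradient magnitudes (the gradient-similarity convention). `w1`
#' weighs the luminance-contrast product against the gradient term in
#' the local fusion `P_s + w1 * P_l * P_c`; `theta` exponentiates that
#' local bracket and `psi` the global contour similarity, setting their
#' relative importance in the pooled score.
#'
#' @param C1,C2,C3,C4 positive stabilisers of the four similarity maps
#'   (contour, luminance, contrast, gradient).
#' @param w1 nonnegative weight of the luminance-contrast product.
#' @param theta positive exponent of the local fusion bracket.
#' @param psi positive exponent of the contour similarity.
#' @param saliency a [saliency_params()].
#' @param window a [window_spec()] for the luminance/contrast
#'   statistics.
#' @param pooling_epsilon guard threshold below which a weight-map sum
#'   counts as zero and pooling falls back to the unweighted mean.
#' @return an `mmiqa_params` list.
#' @export
mmiqa_params <- function(C1 = 1e-4, C2 = (0.01 * 255)^2, C3 = (0.03 * 255)^2,
                         C4 = 170, w1 = 0.6, theta = 1, psi = 1,
                         saliency = saliency_params(),
                         window = window_spec(),
                         pooling_epsilon = 1e-12) {
  for (nm in c("C1", "C2", "C3", "C4", "theta", "pooling_epsilon")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a positive finite scalar", nm), call. = FALSE)
    }
  }
  ## psi = 0 is the degenerate diagnostic mode (contour term switched
  ## off); w1 = 0 likewise drops the luminance-contrast product
  for (nm in c("w1", "psi")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("`%s` must be a nonnegative finite scalar", nm),
           call. = FALSE)
    }
  }
  if (!inherits(saliency, "saliency_params")) {
    stop("`saliency` must be a saliency_params object", call. = FALSE)
  }
  if (!inherits(window, "window_spec")) {
    stop("`window` must be a window_spec object", call. = FALSE)
  }
  structure(list(C1 = C1, C2 = C2, C3 = C3, C4 = C4, w1 = w1,
                 theta = theta, psi = psi, saliency = saliency,
                 window = window, pooling_epsilon = pooling_epsilon),
            class = "mmiqa_params")
}

## ---- flat config serialisation (key: value lines) -------------------

params_to_config <- function(params) {
  s <- params$saliency; w <- params$window
  c(sprintf("c1: %.17g", params$C1), sprintf("c2: %.17g", params$C2),
    sprintf("c3: %.17g", params$C3), sprintf("c4: %.17g", params$C4),
    sprintf("w1: %.17g", params$w1), sprintf("theta: %.17g", params$theta),
    sprintf("psi: %.17g", params$psi),
    sprintf("pooling_epsilon: %.17g", params$pooling_epsilon),
    sprintf("saliency.working_width: %d", s$working_width),
    sprintf("saliency.gamma: %.17g", s$gamma),
    sprintf("saliency.residual_filter_size: %d", s$residual_filter_size),
    sprintf("saliency.smooth_sigma: %.17g", s$smooth_sigma),
    sprintf("saliency.log_epsilon: %.17g", s$log_epsilon),
    sprintf("saliency.stretch_on: %s", s$stretch_on),
    sprintf("window.kind: %s", w$kind),
    sprintf("window.size: %d", w$size),
    sprintf("window.sigma: %.17g", w$sigma))
}

#' Write MM-IQA parameters to a flat config file
#'
#' One `key: value` per line; round-trips losslessly through
#' [read_mmiqa_config()].
#'
#' @param params an [mmiqa_params()].
#' @param path output path.
#' @export
write_mmiqa_config <- function(params, path) {
  writeLines(params_to_config(params), path)
  invisible(path)
}

#' Read MM-IQA parameters from a flat config file
#'
#' Unknown keys are an error (guards against silent typos); omitted
#' keys keep their defaults.
#'
#' @param path config file path.
#' @return an [mmiqa_params()].
#' @export
read_mmiqa_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad)) {
    stop(sprintf("malformed config line: '%s'", bad[1]), call. = FALSE)
  }
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  known_num <- c("c1", "c2", "c3", "c4", "w1", "theta", "psi",
                 "pooling_epsilon", "saliency.working_width",
                 "saliency.gamma", "saliency.residual_filter_size",
                 "saliency.smooth_sigma", "saliency.log_epsilon",
                 "window.size", "window.sigma")
  known_chr <- c("saliency.stretch_on", "window.kind")
  unknown <- setdiff(keys, c(known_num, known_chr))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(keys)) stop("duplicate config keys", call. = FALSE)
  get_num <- function(key, default) {
    if (key %in% keys) as.numeric(vals[keys == key]) else default
  }
  get_chr <- function(key, default) {
    if (key %in% keys) vals[keys == key] else default
  }
  sal <- saliency_params(
    working_width = get_num("saliency.working_width", 256),
    gamma = get_num("saliency.gamma", 1),
    residual_filter_size = get_num("saliency.residual_filter_size", 7),
    smooth_sigma = get_num("saliency.smooth_sigma", 3),
    log_epsilon = get_num("saliency.log_epsilon", 1e-8),
    stretch_on = get_chr("saliency.stretch_on", "log"))
  win <- window_spec(kind = get_chr("window.kind", "gaussian"),
                     size = get_num("window.size", 11),
                     sigma = get_num("window.sigma", 1.5))
  mmiqa_params(C1 = get_num("c1", 1e-4), C2 = get_num("c2", (0.01 * 255)^2),
               C3 = get_num("c3", (0.03 * 255)^2), C4 = get_num("c4", 170),
               w1 = get_num("w1", 0.6), theta = get_num("theta", 1),
               psi = get_num("psi", 1), saliency = sal, window = win,
               pooling_epsilon = get_num("pooling_epsilon", 1e-12))
}

#' Fingerprint of a parameter set
#'
#' Stable short hex digest of the serialised config, recorded with
#' every score so tables can be audited for parameter drift.
#'
#' @param params an [mmiqa_params()].
#' @return an 8-character hex string.
#' @export
params_digest <- function(params) {
  bytes <- utf8ToInt(paste(params_to_config(params), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Saliency-weighted global structure score
#'
#' Pools a contour-similarity map under positional weights:
#' `G_s = sum(Con^psi * w) / sum(w)` over the whole grid. With
#' similarity values in `(0, 1]` the result lies in `(0, 1]`.
#'
#' @param con similarity map (matrix with values in `(0, 1]`).
#' @param weights nonnegative weight matrix, same size.
#' @param psi positive exponent adjusting the importance of structure.
#' @param pooling_epsilon weight-sum threshold under which pooling
#'   falls back to the unweighted mean (with a warning).
#' @return scalar in `(0, 1]`.
#' @export
global_structure <- function(con, weights, psi = 1,
                             pooling_epsilon = 1e-12) {
  con <- as_plain_matrix(as.matrix(con))
  weights <- as_plain_matrix(as.matrix(weights))
  check_same_dim(con, weights, "map and weights")
  if (psi < 0) stop("psi must be nonnegative", call. = FALSE)
  if (min(weights) < 0) stop("weights must be nonnegative", call. = FALSE)
  sw <- sum(weights)
  if (sw <= pooling_epsilon) {
    warning("all-zero weight map: falling back to unweighted mean")
    return(mean(con^psi))
  }
  sum(con^psi * weights) / sw
}

## shared internals of the end-to-end score; returns all stage maps so
## the CLI can report per-term means
mm_iqa_stages <- function(reference, distorted, params,
                          weights_override = NULL) {
  reference <- as_image_plane(reference)
  distorted <- as_image_plane(distorted)
  check_same_dim(reference, distorted, "reference and distorted planes")
  x <- as_plain_matrix(reference)
  y <- as_plain_matrix(distorted)
  sp <- params$saliency

  ## large scale: main-target maps on the working grid
  wd <- saliency_working_dim(nrow(x), ncol(x), sp)
  sal_x <- normalize_saliency(
    spectral_residual_raw(resize_bilinear(x, wd[1], wd[2]), sp))
  sal_y <- normalize_saliency(
    spectral_residual_raw(resize_bilinear(y, wd[1], wd[2]), sp))
  con_w <- similarity_map(sal_x, sal_y, params$C1)
  wmap_w <- positional_weight_map(sal_x, sal_y, sp$smooth_sigma)

  ## bridge the two scales: upsample to the native feature grid
  con <- resize_bilinear(as_plain_matrix(con_w), nrow(x), ncol(x))
  con[con > 1] <- 1; con[con < 0] <- 0
  wmap <- resize_bilinear(wmap_w, nrow(x), ncol(x))
  wmap[wmap < 0] <- 0
  if (!is.null(weights_override)) {
    check_same_dim(weights_override, con, "weight override")
    wmap <- weights_override
  }

  ## small scale: luminance / contrast / gradient similarity
  p_l <- similarity_map(local_mean_map(x, params$window),
                        local_mean_map(y, params$window), params$C2)
  p_c <- similarity_map(local_std_map(x, params$window),
                        local_std_map(y, params$window), params$C3)
  p_s <- similarity_map(scharr_gradient_magnitude(x),
                        scharr_gradient_magnitude(y), params$C4)

  list(sal_ref = sal_x, sal_dist = sal_y, con = con, weights = wmap,
       p_l = p_l, p_c = p_c, p_s = p_s)
}

check_finite_stage <- function(x, stage) {
  if (anyNA(x) || !all(is.finite(x))) {
    stop(sprintf("non-finite values produced at stage '%s'", stage),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' MM-IQA quality score
#'
#' End-to-end metric: spectral-residual saliency of both planes at the
#' working scale gives the contour similarity `Con` and the positional
#' weight map; luminance, contrast and Scharr-gradient similarity maps
#' are computed at native scale; the pooled score is
#'
#' `sum([P_s + w1 P_l P_c]^theta * Con^psi * w) / (sum(w) * (1+w1)^theta)`
#'
#' The division by `(1 + w1)^theta` — the bracket's attainable
#' maximum — bounds the score to `(0, 1]` with 1 attained exactly on
#' identical planes. Rankings are unaffected by this normalisation.
#' Symmetric in its two image arguments and deterministic for fixed
#' parameters.
#'
#' @param reference,distorted [image_plane()]s of equal size.
#' @param params an [mmiqa_params()].
#' @param reference_id,distorted_id labels carried into the result.
#' @param weights_override optional weight matrix replacing the
#'   saliency-derived positional weights (diagnostic use).
#' @return a `quality_score`: list with `value` in `(0, 1]`,
#'   `global_structure` (the pooled contour score, diagnostic), ids and
#'   the parameter digest.
#' @examples
#' img <- generate_pool_fixture(fixture_spec(seed = 3, height = 64, width = 96))
#' mm_iqa_score(img, img)$value  # exactly 1
#' @export
mm_iqa_score <- function(reference, distorted, params = mmiqa_params(),
                         reference_id = "reference",
                         distorted_id = "distorted",
                         weights_override = NULL) {
  st <- mm_iqa_stages(reference, distorted, params, weights_override)
  for (nm in c("con", "weights", "p_l", "p_c", "p_s")) {
    check_finite_stage(st[[nm]], nm)
  }
  bracket <- (as_plain_matrix(st$p_s) +
                params$w1 * as_plain_matrix(st$p_l) *
                as_plain_matrix(st$p_c))^params$theta
  term <- bracket * st$con^params$psi
  sw <- sum(st$weights)
  pooled <- if (sw <= params$pooling_epsilon) {
    warning("all-zero weight map: falling back to unweighted pooling")
    mean(term)
  } else {
    sum(term * st$weights) / sw
  }
  value <- pooled / (1 + params$w1)^params$theta
  check_finite_stage(value, "pooling")
  gs <- if (sw <= params$pooling_epsilon) mean(st$con^params$psi) else
    sum(st$con^params$psi * st$weights) / sw
  structure(list(value = value, global_structure = gs,
                 reference_id = reference_id, distorted_id = distorted_id,
                 params_digest = params_digest(params)),
            class = "quality_score")
}

#' @export
print.quality_score <- function(x, ...) {
  cat(sprintf("MM-IQA(%s, %s) = %.6f  [G_s = %.6f, params %s]\n",
              x$reference_id, x$distorted_id, x$value, x$global_structure,
              x$params_digest))
  invisible(x)
}

#' Score a batch of distortion sets
#'
#' One row per (reference, level) in deterministic order (sets in input
#' order, levels in stored order). A failing pair is recorded as an
#' error row (`score = NA`, message kept) and the batch continues.
#'
#' @param sets list of [build_distortion_set()] objects.
#' @param params an [mmiqa_params()].
#' @return a data.frame with columns `reference_id`, `level`, `score`,
#'   `params_digest`, `error`; attribute `n_failed` counts error rows.
#' @export
mm_iqa_batch <- function(sets, params = mmiqa_params()) {
  if (length(sets) == 0L) stop("`sets` must be a nonempty list",
                               call. = FALSE)
  if (inherits(sets, "distortion_set")) sets <- list(sets)
  digest <- params_digest(params)
  rows <- list()
  n_failed <- 0L
  for (s in sets) {
    for (i in seq_along(s$levels)) {
      res <- tryCatch(
        mm_iqa_score(s$reference, s$distorted[[i]], params,
                     reference_id = s$reference_id,
                     distorted_id = sprintf("%s_q%d", s$reference_id,
                                            s$levels[i])),
        error = function(e) e)
      if (inherits(res, "error")) {
        n_failed <- n_failed + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          reference_id = s$reference_id, level = s$levels[i],
          score = NA_real_, params_digest = digest,
          error = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          reference_id = s$reference_id, level = s$levels[i],
          score = res$value, params_digest = digest, error = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  out
}
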