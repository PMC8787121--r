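#' Rating matrix: subjects x images
#'
#' Raw single-stimulus opinion scores on the continuous `[1, 5]` scale.
#' Missing entries (screened out or never collected) are `NA`.
#'
#' @param scores numeric matrix, rows = subjects, columns = images.
#' @param subject_ids,image_ids label vectors matching the dimensions.
#' @param ref_of named character vector mapping each distorted image id
#'   to its reference image id (may be empty for reference matrices).
#' @return a `rating_matrix` list.
#' @export
rating_matrix <- function(scores, subject_ids = NULL, image_ids = NULL,
                          ref_of = character(0)) {
  scores <- as.matrix(scores)
  if (is.null(subject_ids)) {
    subject_ids <- rownames(scores)
    if (is.null(subject_ids)) subject_ids <- sprintf("s%02d",
                                                     seq_len(nrow(scores)))
  }
  if (is.null(image_ids)) {
    image_ids <- colnames(scores)
    if (is.null(image_ids)) image_ids <- sprintf("img%04d",
                                                 seq_len(ncol(scores)))
  }
  if (length(subject_ids) != nrow(scores) ||
      length(image_ids) != ncol(scores)) {
    stop("label lists must match the score matrix dimensions", call. = FALSE)
  }
  ok <- is.na(scores) | (scores >= 1 & scores <= 5)
  if (!all(ok)) stop("non-missing scores must lie in [1, 5]", call. = FALSE)
  dimnames(scores) <- list(subject_ids, image_ids)
  structure(list(scores = scores, subject_ids = as.character(subject_ids),
                 image_ids = as.character(image_ids), ref_of = ref_of),
            class = "rating_matrix")
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat(sprintf("<rating_matrix> %d subjects x %d images, %d missing\n",
              nrow(x$scores), ncol(x$scores), sum(is.na(x$scores))))
  invisible(x)
}

#' Screen outlier opinion scores
#'
#' Per image (column), a score is discarded when it deviates from the
#' column mean by more than `k` sample standard deviations (computed
#' over the non-missing scores with the `1/(N-1)` correction). Columns
#' with zero spread keep all scores. Removal changes the column mean
#' and deviation, so the rule is applied repeatedly until no score
#' moves — the fixed point makes the operation idempotent for fixed
#' `k`. Retained scores are unchanged. The default `k = 2` is
#' the usual subjective-database practice; `k = 1` gives the literal
#' one-standard-deviation reading (and would discard roughly a third of
#' honest Gaussian scores).
#'
#' @param ratings a [rating_matrix()].
#' @param k positive threshold in standard-deviation units.
#' @return a [rating_matrix()] with outliers set to `NA`.
#' @export
screen_outliers <- function(ratings, k = 2) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  sc <- ratings$scores
  if (nrow(sc) < 2L) stop("need at least 2 subjects per image", call. = FALSE)
  for (j in seq_len(ncol(sc))) {
    repeat {
      col <- sc[, j]
      keep <- !is.na(col)
      if (sum(keep) < 2L) break
      mu <- mean(col[keep])
      sdv <- stats::sd(col[keep])
      if (is.na(sdv) || sdv == 0) break
      out <- keep & abs(col - mu) > k * sdv
      if (!any(out)) break
      if (all(is.na(col) | out)) {
        stop(sprintf("screening left image '%s' with zero retained scores",
                     ratings$image_ids[j]), call. = FALSE)
      }
      sc[out, j] <- NA
    }
  }
  rating_matrix(sc, ratings$subject_ids, ratings$image_ids, ratings$ref_of)
}

#' Differential mean opinion scores (DMOS)
#'
#' For every distorted image: screen its column with [screen_outliers()]
#' at threshold `k`, form per-subject differential scores
#' `D = reference score - distorted score`, and average over the
#' retained subjects. Larger DMOS means worse quality.
#'
#' @param ratings distorted-image [rating_matrix()] whose `ref_of` maps
#'   each image id to a column of `reference_scores`.
#' @param reference_scores [rating_matrix()] of reference-image scores
#'   over the same subjects (a constant-5 matrix encodes the
#'   "references are perfect" reading).
#' @param k screening threshold, see [screen_outliers()].
#' @return a data.frame with one row per distorted image (input order):
#'   `image_id`, `dmos`, `n_retained`.
#' @export
compute_dmos <- function(ratings, reference_scores, k = 2) {
  if (!setequal(ratings$subject_ids, reference_scores$subject_ids)) {
    stop("ratings and reference_scores must share a subject set",
         call. = FALSE)
  }
  missing_ref <- setdiff(unname(ratings$ref_of[ratings$image_ids]), c(
    reference_scores$image_ids))
  if (length(ratings$ref_of) < length(ratings$image_ids) ||
      !all(ratings$image_ids %in% names(ratings$ref_of))) {
    stop("every distorted image needs a ref_of entry", call. = FALSE)
  }
  if (length(missing_ref)) {
    stop(sprintf("reference id(s) not found in reference_scores: %s",
                 paste(missing_ref, collapse = ", ")), call. = FALSE)
  }
  screened <- screen_outliers(ratings, k)
  ## align reference rows to the distorted matrix's subject order
  ref_sc <- reference_scores$scores[match(ratings$subject_ids,
                                          reference_scores$subject_ids), ,
                                    drop = FALSE]
  out <- lapply(seq_along(ratings$image_ids), function(j) {
    id <- ratings$image_ids[j]
    dist_col <- screened$scores[, j]
    ref_col <- ref_sc[, ratings$ref_of[[id]]]
    keep <- !is.na(dist_col) & !is.na(ref_col)
    if (!any(keep)) {
      stop(sprintf("no retained subject pairs for image '%s'", id),
           call. = FALSE)
    }
    d <- ref_col[keep] - dist_col[keep]
    data.frame(image_id = id, dmos = mean(d), n_retained = sum(keep),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a single-stimulus rating experiment
#'
#' Test stand-in for a viewing session: true quality `q` on `[0, 1]`
#' maps to a latent opinion `1 + 4 q`; each subject carries a Gaussian
#' bias, each score Gaussian noise; a Bernoulli fraction of scores is
#' replaced by uniform random values on `[1, 5]` (attention lapses);
#' everything is clipped to `[1, 5]`. The reference matrix is generated
#' by the same process at true quality 1. Deterministic per seed.
#'
#' @param true_quality vector of latent qualities in `[0, 1]`, one per
#'   distorted image.
#' @param n_subjects number of observers (>= 2; the protocol this
#'   mirrors used 16).
#' @param subject_bias_sd,noise_sd Gaussian scales of per-subject bias
#'   and per-score noise, in opinion-scale units.
#' @param outlier_rate probability a score is an attention-lapse
#'   outlier.
#' @param seed integer RNG seed.
#' @return list with `distorted` and `reference` [rating_matrix()]s;
#'   `distorted` carries a logical attribute `outlier_mask` marking the
#'   planted outliers.
#' @export
simulate_ratings <- function(true_quality, n_subjects = 16L,
                             subject_bias_sd = 0.2, noise_sd = 0.2,
                             outlier_rate = 0, seed = 1L) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  if (any(true_quality < 0 | true_quality > 1)) {
    stop("true_quality values must lie in [0, 1]", call. = FALSE)
  }
  if (outlier_rate < 0 || outlier_rate > 1) {
    stop("outlier_rate must lie in [0, 1]", call. = FALSE)
  }
  n_img <- length(true_quality)
  with_seed(seed, {
    bias <- stats::rnorm(n_subjects, sd = subject_bias_sd)
    gen <- function(q) {
      latent <- matrix(rep(1 + 4 * q, each = n_subjects), n_subjects,
                       length(q))
      raw <- latent + bias +
        matrix(stats::rnorm(n_subjects * length(q), sd = noise_sd),
               n_subjects, length(q))
      mask <- matrix(stats::runif(n_subjects * length(q)) < outlier_rate,
                     n_subjects, length(q))
      raw[mask] <- stats::runif(sum(mask), 1, 5)
      list(scores = pmin(pmax(raw, 1), 5), mask = mask)
    }
    d <- gen(true_quality)
    r <- gen(rep(1, n_img))
    img_ids <- sprintf("dist%04d", seq_len(n_img))
    ref_ids <- sprintf("ref%04d", seq_len(n_img))
    dist_rm <- rating_matrix(d$scores,
                             subject_ids = sprintf("s%02d",
                                                   seq_len(n_subjects)),
                             image_ids = img_ids,
                             ref_of = stats::setNames(ref_ids, img_ids))
    attr(dist_rm, "outlier_mask") <- d$mask
    ref_rm <- rating_matrix(r$scores,
                            subject_ids = sprintf("s%02d",
                                                  seq_len(n_subjects)),
                            image_ids = ref_ids)
    list(distorted = dist_rm, reference = ref_rm)
  })
}

## ---- CSV dialect: rows = subjects, first column = subject id --------

#' Read a rating CSV (rows = subjects, columns = images)
#' @param path ratings CSV; first column is the subject id.
#' @param refs_path optional sidecar CSV with columns
#'   `image_id,reference_id`.
#' @return a [rating_matrix()].
#' @export
read_ratings_csv <- function(path, refs_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  subject_ids <- as.character(df[[1]])
  sc <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(sc) <- "double"
  ref_of <- character(0)
  if (!is.null(refs_path)) {
    rf <- utils::read.csv(refs_path, stringsAsFactors = FALSE)
    ref_of <- stats::setNames(as.character(rf$reference_id),
                              as.character(rf$image_id))
  }
  rating_matrix(sc, subject_ids, colnames(sc), ref_of)
}

#' Write a rating CSV
#' @param ratings a [rating_matrix()].
#' @param path output CSV path.
#' @export
write_ratings_csv <- function(ratings, path) {
  df <- data.frame(subject_id = ratings$subject_ids,
                   ratings$scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
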