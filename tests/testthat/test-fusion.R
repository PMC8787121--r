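test_that("global_structure pools as a weighted mean", {
  ## worked 1x2 example: (0.25*1 + 1*3) / 4 = 0.8125
  con <- matrix(c(0.5, 1.0), 1, 2)
  w <- matrix(c(1, 3), 1, 2)
  expect_equal(global_structure(con, w, psi = 2), 0.8125, tolerance = 1e-12)
  ## ones pool to 1 under any weights; one-hot weights select a pixel
  set.seed(51)
  anyw <- matrix(runif(12), 3, 4)
  expect_equal(global_structure(matrix(1, 3, 4), anyw, psi = 1.7), 1,
               tolerance = 1e-12)
  onehot <- matrix(0, 3, 4); onehot[2, 3] <- 1
  con2 <- matrix(runif(12, 0.1, 1), 3, 4)
  expect_equal(global_structure(con2, onehot, psi = 1), con2[2, 3],
               tolerance = 1e-12)
  ## all-zero weights fall back to the unweighted mean, with a warning
  expect_warning(gz <- global_structure(con2, matrix(0, 3, 4), psi = 1),
                 "all-zero")
  expect_equal(gz, mean(con2), tolerance = 1e-12)
  expect_error(global_structure(con2, matrix(1, 2, 2)), "dimensions")
})

test_that("identical planes score exactly 1 across the parameter grid", {
  for (p in params_grid()) {
    img <- small_fixture(seed = 61)
    sc <- mm_iqa_score(img, img, p)
    expect_lt(abs(sc$value - 1), 1e-9)
    expect_lt(abs(sc$global_structure - 1), 1e-9)
  }
})

test_that("the score is symmetric in its arguments", {
  x <- small_fixture(seed = 62)
  y <- small_fixture(seed = 63)
  for (p in params_grid()) {
    expect_lt(abs(mm_iqa_score(x, y, p)$value -
                    mm_iqa_score(y, x, p)$value), 1e-9)
  }
})

test_that("scores live in (0,1] on random pairs", {
  for (seed in 1:12) {
    x <- random_plane(seed, 32, 48)
    y <- random_plane(seed + 100, 32, 48)
    v <- mm_iqa_score(x, y, fast_params())$value
    expect_gt(v, 0)
    expect_lte(v, 1 + 1e-12)
  }
})

test_that("w1=0, theta=1, psi=0, uniform weights reduce to mean P_s", {
  x <- small_fixture(seed = 64)
  y <- generate_pool_fixture(fixture_spec(seed = 64, height = 96,
                                          width = 128, noise_sd = 6))
  p <- mmiqa_params(w1 = 0, theta = 1, psi = 0)
  uni <- matrix(1, nrow(x), ncol(x))
  direct <- mean(as_plain_matrix(similarity_map(
    scharr_gradient_magnitude(as_plain_matrix(x)),
    scharr_gradient_magnitude(as_plain_matrix(y)), p$C4)))
  got <- mm_iqa_score(x, y, p, weights_override = uni)$value
  expect_equal(got, direct, tolerance = 1e-12)
})

test_that("saliency weighting emphasises salient-region corruption", {
  ## Contrast masking means equal-energy noise moves P_s far more in
  ## flat (non-salient) regions than on busy edges, so the raw
  ## cross-comparison "corrupt hi-decile scores below corrupt
  ## lo-decile" does not hold for any GMS-family similarity. The
  ## pooling property itself is tested controlled for masking: for the
  ## SAME corruption, saliency weights must pull the score towards the
  ## corrupted decile's local similarity relative to uniform pooling.
  img <- small_fixture(seed = 65, n_swimmers = 3)
  p <- fast_params()
  sal <- spectral_residual_saliency(img, p$saliency)
  q <- stats::quantile(sal, c(0.1, 0.9))
  hi <- sal >= q[2]
  lo <- sal <= q[1]
  n <- min(sum(hi), sum(lo))
  set.seed(66)
  noise <- rnorm(n, sd = 25)
  corrupt <- function(mask) {
    m <- as_plain_matrix(img)
    idx <- which(mask)[seq_len(n)]
    prop <- m[idx] + noise
    flip <- prop > 255 | prop < 0   # reflect noise that would clip
    prop[flip] <- m[idx][flip] - noise[flip]
    m[idx] <- pmin(pmax(prop, 0), 255)
    image_plane(m)
  }
  uni <- matrix(1, nrow(img), ncol(img))
  ch <- corrupt(hi)
  cl <- corrupt(lo)
  ## the weight mass actually concentrates on the salient decile
  st <- mmiqa:::mm_iqa_stages(img, ch, p)
  expect_gt(mean(st$weights[hi]), 5 * mean(st$weights[lo]))
  ## salient corruption: weighting lowers the score vs uniform pooling
  expect_lt(mm_iqa_score(img, ch, p)$value,
            mm_iqa_score(img, ch, p, weights_override = uni)$value)
  ## non-salient corruption: weighting raises it vs uniform pooling
  expect_gt(mm_iqa_score(img, cl, p)$value,
            mm_iqa_score(img, cl, p, weights_override = uni)$value)
})

test_that("batch scoring is deterministic, ordered and fault-tolerant", {
  expect_python()
  img1 <- small_fixture(seed = 71, height = 48, width = 64)
  img2 <- small_fixture(seed = 72, height = 48, width = 64)
  p <- fast_params()
  sets <- list(build_distortion_set(img1, c(50, 10), "a"),
               build_distortion_set(img2, c(50, 10), "b"))
  tab <- mm_iqa_batch(sets, p)
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$reference_id, c("a", "a", "b", "b"))
  expect_identical(tab$level, c(50L, 10L, 50L, 10L))
  expect_identical(attr(tab, "n_failed"), 0L)
  tab2 <- mm_iqa_batch(sets, p)
  expect_identical(tab$score, tab2$score)
  expect_identical(tab$params_digest[1], params_digest(p))

  ## identical pairs -> all scores 1
  idset <- list(reference_id = "id", reference = img1, levels = 1L,
                distorted = list(img1))
  class(idset) <- "distortion_set"
  expect_lt(abs(mm_iqa_batch(list(idset), p)$score - 1), 1e-9)

  ## a failing pair becomes an error row, batch continues
  bad <- idset
  bad$distorted <- list(small_fixture(seed = 1, height = 24, width = 24))
  tab3 <- mm_iqa_batch(list(bad, idset), p)
  expect_identical(attr(tab3, "n_failed"), 1L)
  expect_true(is.na(tab3$score[1]) && nzchar(tab3$error[1]))
  expect_false(is.na(tab3$score[2]))
})

test_that("params round-trip through the config file; typos are errors", {
  p <- mmiqa_params(C1 = 2e-4, w1 = 0.9, theta = 1.3, psi = 0.8,
                    saliency = saliency_params(working_width = 128,
                                               gamma = 1.4,
                                               smooth_sigma = 2.5,
                                               stretch_on = "amplitude"),
                    window = window_spec("box", size = 7))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_mmiqa_config(p, f)
  q <- read_mmiqa_config(f)
  expect_identical(params_digest(p), params_digest(q))
  expect_equal(q$saliency$gamma, 1.4)
  expect_identical(q$window$kind, "box")

  writeLines(c("w1: 0.5", "w2: 0.1"), f)
  expect_error(read_mmiqa_config(f), "unknown config key.*w2")
  writeLines(c("w1: 0.5", "w1: 0.6"), f)
  expect_error(read_mmiqa_config(f), "duplicate")
})

test_that("mmiqa_params validates constants", {
  expect_error(mmiqa_params(C1 = 0), "positive")
  expect_error(mmiqa_params(w1 = -0.1), "nonnegative")
  expect_error(mmiqa_params(theta = -1), "positive")
  expect_error(mm_iqa_score(small_fixture(1, 24, 24),
                            small_fixture(1, 24, 32)), "dimensions")
})
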