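mk_ratings <- function(scores, ...) rating_matrix(scores, ...)

test_that("screening matches the hand-worked columns", {
  ## column {2,2,2,2,5}: mean 2.6, sample sd 1.3416; 2.4 < 2*sd keeps 5,
  ## 2.4 > 1*sd removes it
  col <- matrix(c(2, 2, 2, 2, 5), 5, 1)
  r <- mk_ratings(col)
  expect_identical(unname(screen_outliers(r, k = 2)$scores[, 1]), col[, 1])
  r1 <- screen_outliers(r, k = 1)
  expect_true(is.na(r1$scores[5, 1]))
  expect_identical(unname(r1$scores[1:4, 1]), rep(2, 4))

  ## zero-spread column keeps everything
  ru <- mk_ratings(matrix(3, 4, 2))
  expect_identical(screen_outliers(ru, k = 1)$scores, ru$scores)

  expect_error(screen_outliers(mk_ratings(matrix(3, 1, 2))), "2 subjects")
  expect_error(screen_outliers(mk_ratings(matrix(3, 4, 2)), k = 0),
               "positive")
})

test_that("screening is idempotent on its own output", {
  sim <- simulate_ratings(seq(0, 1, length.out = 40), n_subjects = 16,
                          subject_bias_sd = 0.2, noise_sd = 0.2,
                          outlier_rate = 0.1, seed = 42)
  once <- screen_outliers(sim$distorted, k = 2)
  twice <- screen_outliers(once, k = 2)
  expect_identical(once$scores, twice$scores)
})

test_that("DMOS arithmetic follows reference minus distorted", {
  ## one subject: reference 5, distorted 3 -> D = 2
  d <- mk_ratings(matrix(c(3, 3), 2, 1, dimnames = list(NULL, "d1")),
                  ref_of = c(d1 = "r1"))
  r <- mk_ratings(matrix(c(5, 5), 2, 1, dimnames = list(NULL, "r1")))
  expect_equal(compute_dmos(d, r, k = 2)$dmos, 2)

  ## D values {2,2,4} -> 8/3
  d3 <- mk_ratings(matrix(c(3, 3, 1), 3, 1, dimnames = list(NULL, "d1")),
                   ref_of = c(d1 = "r1"))
  r3 <- mk_ratings(matrix(5, 3, 1, dimnames = list(NULL, "r1")))
  expect_equal(compute_dmos(d3, r3, k = 10)$dmos, 8 / 3)

  ## distorted == reference -> dmos 0
  same <- matrix(c(4, 3, 5), 3, 1)
  d0 <- mk_ratings(matrix(same, dimnames = list(NULL, "d1")),
                   ref_of = c(d1 = "r1"))
  r0 <- mk_ratings(matrix(same, dimnames = list(NULL, "r1")))
  expect_equal(compute_dmos(d0, r0, k = 5)$dmos, 0)

  ## unmatched reference id
  dbad <- mk_ratings(matrix(3, 3, 1, dimnames = list(NULL, "d1")),
                     ref_of = c(d1 = "nope"))
  expect_error(compute_dmos(dbad, r0), "nope")
})

test_that("DMOS is invariant to subject and image ordering", {
  sim <- simulate_ratings(c(0.2, 0.5, 0.9), n_subjects = 8, seed = 7,
                          noise_sd = 0.3, subject_bias_sd = 0.2)
  base <- compute_dmos(sim$distorted, sim$reference, k = 2)
  ## permute subjects in both matrices, images in the distorted one
  perm_s <- c(5, 3, 8, 1, 7, 2, 6, 4)
  perm_i <- c(3, 1, 2)
  d2 <- rating_matrix(sim$distorted$scores[perm_s, perm_i],
                      sim$distorted$subject_ids[perm_s],
                      sim$distorted$image_ids[perm_i],
                      sim$distorted$ref_of)
  r2 <- rating_matrix(sim$reference$scores[perm_s, ],
                      sim$reference$subject_ids[perm_s],
                      sim$reference$image_ids)
  got <- compute_dmos(d2, r2, k = 2)
  expect_equal(got$dmos[match(base$image_id, got$image_id)], base$dmos,
               tolerance = 1e-12)
})

test_that("the rating simulator honours its contract", {
  ## noiseless world: q = 0.5 scores exactly 3 everywhere
  s <- simulate_ratings(0.5, n_subjects = 4, subject_bias_sd = 0,
                        noise_sd = 0, outlier_rate = 0, seed = 1)
  expect_true(all(s$distorted$scores == 3))
  expect_true(all(s$reference$scores == 5))

  ## determinism per seed
  a <- simulate_ratings(c(0.1, 0.8), n_subjects = 6, outlier_rate = 0.2,
                        seed = 9)
  b <- simulate_ratings(c(0.1, 0.8), n_subjects = 6, outlier_rate = 0.2,
                        seed = 9)
  expect_identical(a$distorted$scores, b$distorted$scores)
  expect_identical(a$reference$scores, b$reference$scores)

  expect_error(simulate_ratings(0.5, n_subjects = 1), ">= 2")
  expect_error(simulate_ratings(1.5), "\\[0, 1\\]")
})

test_that("screening removes planted outliers more than clean scores", {
  sim <- simulate_ratings(runif(50), n_subjects = 20, subject_bias_sd = 0.1,
                          noise_sd = 0.15, outlier_rate = 0.1, seed = 11)
  mask <- attr(sim$distorted, "outlier_mask")
  screened <- screen_outliers(sim$distorted, k = 2)
  removed <- is.na(screened$scores)
  frac_outliers_caught <- sum(removed & mask) / sum(mask)
  frac_clean_removed <- sum(removed & !mask) / sum(!mask)
  expect_gt(frac_outliers_caught, frac_clean_removed)
})

test_that("low-noise DMOS recovers the simulated quality ranking", {
  set.seed(13)
  q <- runif(25)
  sim <- simulate_ratings(q, n_subjects = 16, subject_bias_sd = 0.2,
                          noise_sd = 0.2, outlier_rate = 0.1, seed = 13)
  dm <- compute_dmos(sim$distorted, sim$reference, k = 2)
  expect_gt(srocc(q, -dm$dmos), 0.9)
})

test_that("rating CSVs round-trip through the documented dialect", {
  sim <- simulate_ratings(c(0.3, 0.7), n_subjects = 5, seed = 3,
                          outlier_rate = 0.05)
  tdir <- withr::local_tempdir()
  rcsv <- file.path(tdir, "ratings.csv")
  refcsv <- file.path(tdir, "refs.csv")
  write_ratings_csv(sim$distorted, rcsv)
  utils::write.csv(data.frame(image_id = sim$distorted$image_ids,
                              reference_id = unname(sim$distorted$ref_of)),
                   refcsv, row.names = FALSE)
  back <- read_ratings_csv(rcsv, refcsv)
  expect_equal(back$scores, sim$distorted$scores, tolerance = 1e-12)
  expect_identical(unname(back$ref_of[back$image_ids]),
                   unname(sim$distorted$ref_of[sim$distorted$image_ids]))
})
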