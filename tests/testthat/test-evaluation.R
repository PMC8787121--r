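test_that("logistic_map evaluates the five-parameter curve", {
  ## q = tau3 zeroes the bracket: S = tau3*tau4 + tau5
  tau <- c(3, 0.7, 1.2, 0.4, -0.5)
  expect_equal(logistic_map(1.2, tau), 1.2 * 0.4 - 0.5, tolerance = 1e-12)
  ## tau1 = tau4 = 0: constant tau5
  expect_equal(logistic_map(seq(-5, 5), c(0, 1, 0, 0, 2.5)), rep(2.5, 11))
  ## hand case: tau = (2,1,0,0.5,1) at q = 0 -> 1
  expect_equal(logistic_map(0, c(2, 1, 0, 0.5, 1)), 1, tolerance = 1e-12)
  expect_error(logistic_map(1, c(1, 0, 1, 1, 1)), "nonzero")
  expect_error(logistic_map(1, c(1, 1, 1)), "five")
})

test_that("fit_logistic recovers a generating curve and is idempotent", {
  set.seed(71)
  q <- sort(runif(50, -2, 3))
  tau_true <- c(2.5, 0.6, 0.5, 0.3, 1.0)
  s <- logistic_map(q, tau_true)
  fit <- fit_logistic(q, s)
  expect_lt(fit$rmse, 1e-6)
  expect_lt(max(abs(logistic_map(q, fit$tau) - s)), 1e-5)

  ## refit on the fitted curve's own outputs: RMSE change < 1e-8
  mapped <- logistic_map(q, fit$tau)
  fit2 <- fit_logistic(q, mapped)
  expect_lt(abs(fit2$rmse - 0), 1e-8)

  ## constant subjective data is fit exactly
  fitc <- fit_logistic(q, rep(2, 50))
  expect_lt(max(abs(logistic_map(q, fitc$tau) - 2)), 1e-6)

  ## decreasing relations fit as well as increasing ones
  fit_dec <- fit_logistic(q, logistic_map(q, c(2.5, -0.6, 0.5, -0.1, 1)))
  expect_lt(fit_dec$rmse, 1e-6)

  expect_error(fit_logistic(1:4, 1:4), "at least 5")
  expect_error(fit_logistic(rep(1, 6), 1:6), "degenerate")
})

test_that("fit_logistic never loses to its own initialisation", {
  set.seed(72)
  for (i in 1:5) {
    q <- runif(30, 0, 1)
    s <- 4 - 3 * q + rnorm(30, sd = 0.5)
    fit <- fit_logistic(q, s)
    init <- c(max(s) - min(s), -sd(q) / 4, median(q), 0, mean(s))
    expect_lte(fit$rmse,
               sqrt(mean((logistic_map(q, init) - s)^2)) + 1e-12)
  }
})

test_that("srocc matches closed form and brute-force ranking", {
  expect_equal(srocc(1:4, c(1, 2, 4, 3)), 0.8, tolerance = 1e-12)
  expect_equal(srocc(1:6, exp(1:6)), 1)
  expect_equal(srocc(1:6, -(1:6)^3), -1)
  set.seed(73)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    a <- sample(round(runif(n, 0, 20) * 2) / 2)  # ties likely
    b <- round(runif(n, 0, 10))
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(srocc(a, b), oracle_srocc(a, b), tolerance = 1e-12)
  }
  expect_error(srocc(c(1, 1, 1), 1:3), "degenerate")
})

test_that("krocc is exactly brute-force tau-b pair counting", {
  expect_equal(krocc(1:3, c(1, 3, 2)), 1 / 3, tolerance = 1e-12)
  expect_equal(krocc(1:5, 2 * (1:5) + 1), 1)
  set.seed(74)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    a <- round(runif(n, 0, 8))
    b <- round(runif(n, 0, 8))
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(krocc(a, b), oracle_krocc(a, b), tolerance = 1e-12)
  }
})

test_that("rank correlations ignore strictly monotone transforms", {
  set.seed(75)
  a <- runif(30); b <- runif(30)
  f <- function(x) exp(3 * x) - 1
  expect_equal(srocc(f(a), b), srocc(a, b), tolerance = 1e-12)
  expect_equal(krocc(a, f(b)), krocc(a, b), tolerance = 1e-12)
})

test_that("plcc_rmse_mae matches hand arithmetic", {
  r <- plcc_rmse_mae(c(0, 2, 1), c(0, 0, 1))
  expect_equal(r$rmse, sqrt(mean(c(0, 4, 0))), tolerance = 1e-12)
  expect_equal(r$mae, mean(c(0, 2, 0)), tolerance = 1e-12)
  same <- plcc_rmse_mae(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(same), c(plcc = 1, rmse = 0, mae = 0))
  aff <- plcc_rmse_mae(c(1, 2, 3, 4), 2 * c(1, 2, 3, 4) - 5)
  expect_equal(aff$plcc, 1, tolerance = 1e-12)
  expect_warning(z <- plcc_rmse_mae(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(z$plcc))
  expect_equal(z$rmse, sqrt(mean(c(0, 1, 4))), tolerance = 1e-12)
})

test_that("evaluate_metric wires the indices together", {
  set.seed(76)
  q <- sort(runif(40, 0, 1))
  dmos <- logistic_map(q, c(3, -0.2, 0.5, -0.5, 2))  # smooth decreasing
  rep <- evaluate_metric(q, dmos)
  expect_equal(rep$srocc, -1)
  expect_equal(rep$krocc, -1)
  expect_gt(abs(rep$plcc), 0.999)
  expect_identical(rep$n, 40L)

  ## objective duplicated as dmos: all indices perfect
  perfect <- evaluate_metric(q, q)
  expect_equal(perfect$srocc, 1)
  expect_equal(perfect$plcc, 1, tolerance = 1e-9)
  expect_lt(perfect$rmse, 1e-7)

  ## permutation invariance
  perm <- sample(40)
  rep2 <- evaluate_metric(q[perm], dmos[perm])
  expect_equal(rep2$srocc, rep$srocc, tolerance = 1e-12)
  expect_equal(rep2$rmse, rep$rmse, tolerance = 1e-9)
})

test_that("baseline MSE/PSNR behave", {
  a <- image_plane(matrix(0, 4, 4))
  b <- image_plane(matrix(255, 4, 4))
  r <- baseline_scores(a, b)
  expect_equal(r$mse, 65025)
  expect_equal(r$psnr, 0)
  expect_identical(baseline_scores(a, a)$psnr, Inf)
  expect_equal(baseline_scores(b, a)$mse, r$mse)
  expect_error(baseline_scores(a, image_plane(matrix(0, 5, 5))),
               "dimensions")
})
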