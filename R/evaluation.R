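#' Five-parameter logistic mapping
#'
#' The standard monotone curve aligning an objective metric's scale
#' with subjective scores before accuracy indices are computed:
#'
#' `S(q) = tau1 * (1/2 - 1/(1 + exp((q - tau3) / tau2))) + tau4 q + tau5`
#'
#' @param q numeric vector of objective scores.
#' @param tau numeric vector of the five regression parameters.
#' @return `S(q)`, elementwise.
#' @export
logistic_map <- function(q, tau) {
  if (length(tau) != 5L || anyNA(tau) || !all(is.finite(tau))) {
    stop("tau must be five finite reals", call. = FALSE)
  }
  if (tau[2] == 0) stop("tau2 must be nonzero", call. = FALSE)
  ## clamp the exponent to dodge overflow; the curve saturates anyway
  z <- pmin(pmax((q - tau[3]) / tau[2], -700), 700)
  tau[1] * (0.5 - 1 / (1 + exp(z))) + q * tau[4] + tau[5]
}

logistic_rmse <- function(tau, q, s) {
  sqrt(mean((logistic_map(q, tau) - s)^2))
}

#' Fit the five-parameter logistic curve
#'
#' Least squares minimisation of `sum((S(q_i) - subjective_i)^2)`.
#' Deterministic: initialisation is `tau1 = range(subjective)`,
#' `tau2 = sd(objective)/4` signed by the raw Pearson correlation,
#' `tau3 = median(objective)`, `tau4 = 0`, `tau5 = mean(subjective)`,
#' plus one restart with `tau2` negated; each start is polished by
#' quasi-Newton then Nelder-Mead, and the best achieved RMSE wins (ties
#' go to the first candidate). The result never has larger RMSE than
#' the best raw initialisation.
#'
#' @param objective,subjective equal-length numeric vectors, `n >= 5`;
#'   `objective` must not be constant.
#' @return list with `tau` (length 5), `rmse` (achieved), `converged`
#'   (logical).
#' @export
fit_logistic <- function(objective, subjective) {
  q <- as.numeric(objective); s <- as.numeric(subjective)
  if (length(q) != length(s)) stop("input lengths differ", call. = FALSE)
  if (length(q) < 5L) stop("need at least 5 points", call. = FALSE)
  if (anyNA(q) || anyNA(s)) stop("inputs must be complete", call. = FALSE)
  if (stats::sd(q) == 0) stop("objective scores are all equal (degenerate)",
                              call. = FALSE)
  rho <- suppressWarnings(stats::cor(q, s))
  sgn <- if (!is.na(rho) && rho < 0) -1 else 1
  t2 <- sgn * max(stats::sd(q) / 4, .Machine$double.eps)
  init1 <- c(max(s) - min(s), t2, stats::median(q), 0, mean(s))
  init2 <- init1 * c(1, -1, 1, 1, 1)
  candidates <- list(init1, init2)

  polish <- function(par) {
    obj <- function(p) {
      if (p[2] == 0) return(.Machine$double.xmax)
      r <- logistic_rmse(p, q, s)
      if (!is.finite(r)) .Machine$double.xmax else r
    }
    fit <- tryCatch(stats::optim(par, obj, method = "BFGS",
                                 control = list(maxit = 500,
                                                reltol = 1e-14)),
                    error = function(e) list(par = par, convergence = 1L))
    fit2 <- tryCatch(stats::optim(fit$par, obj, method = "Nelder-Mead",
                                  control = list(maxit = 4000,
                                                 reltol = 1e-15)),
                     error = function(e) fit)
    fit3 <- tryCatch(stats::optim(fit2$par, obj, method = "BFGS",
                                  control = list(maxit = 500,
                                                 reltol = 1e-14)),
                     error = function(e) fit2)
    list(par = fit3$par, rmse = obj(fit3$par),
         converged = identical(fit3$convergence, 0L))
  }

  results <- lapply(candidates, polish)
  ## monotone acceptance: raw initialisations compete too
  for (cand in candidates) {
    results[[length(results) + 1L]] <- list(par = cand,
                                            rmse = logistic_rmse(cand, q, s),
                                            converged = TRUE)
  }
  rmses <- vapply(results, `[[`, 0, "rmse")
  best <- results[[which.min(rmses)]]
  list(tau = unname(best$par), rmse = best$rmse, converged = best$converged)
}

#' Spearman rank-order correlation
#'
#' Pearson correlation of (average-tie) ranks; measures prediction
#' monotonicity irrespective of scale.
#'
#' @param a,b equal-length numeric vectors, `n >= 3`.
#' @return value in `[-1, 1]`.
#' @export
srocc <- function(a, b) {
  check_rank_inputs(a, b)
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    stop("degenerate input: zero rank variance", call. = FALSE)
  }
  stats::cor(ra, rb)
}

#' Kendall rank-order correlation (tau-b)
#'
#' `(concordant - discordant) / sqrt((n0 - t_a)(n0 - t_b))` with
#' `n0 = n(n-1)/2` and tie corrections `t_a`, `t_b`; identical to
#' brute-force pair counting.
#'
#' @inheritParams srocc
#' @return value in `[-1, 1]`.
#' @export
krocc <- function(a, b) {
  check_rank_inputs(a, b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("degenerate input: zero rank variance", call. = FALSE)
  }
  da <- sign(outer(a, a, "-"))
  db <- sign(outer(b, b, "-"))
  up <- upper.tri(da)
  s <- da[up] * db[up]
  nc <- sum(s > 0); nd <- sum(s < 0)
  n0 <- sum(up)
  ta <- n0 - sum(da[up] != 0)
  tb <- n0 - sum(db[up] != 0)
  (nc - nd) / sqrt((n0 - ta) * (n0 - tb))
}

check_rank_inputs <- function(a, b) {
  if (length(a) != length(b)) stop("input lengths differ", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 points", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("inputs must be complete", call. = FALSE)
  invisible(TRUE)
}

#' Pearson correlation, RMSE and MAE of mapped scores
#'
#' Accuracy/consistency indices between logistic-mapped objective
#' scores and subjective scores. Note on naming: result tables in this
#' field often print the mean absolute error under the heading "MSE";
#' here it is always reported as `mae`.
#'
#' @param mapped logistic-mapped objective scores.
#' @param subjective subjective scores.
#' @return list with `plcc`, `rmse`, `mae`. If either input has zero
#'   variance, or fewer than 3 points are supplied, `plcc` is `NA` with
#'   a warning (RMSE/MAE are still returned — they are well defined
#'   from 2 points).
#' @export
plcc_rmse_mae <- function(mapped, subjective) {
  if (length(mapped) != length(subjective)) stop("input lengths differ",
                                                 call. = FALSE)
  if (length(mapped) < 2L) stop("need at least 2 points", call. = FALSE)
  rmse <- sqrt(mean((mapped - subjective)^2))
  mae <- mean(abs(mapped - subjective))
  if (length(mapped) < 3L || stats::sd(mapped) == 0 ||
      stats::sd(subjective) == 0) {
    warning("zero variance or too few points: PLCC undefined")
    return(list(plcc = NA_real_, rmse = rmse, mae = mae))
  }
  list(plcc = stats::cor(mapped, subjective), rmse = rmse, mae = mae)
}

#' Evaluate an objective metric against subjective scores
#'
#' The standard IQA evaluation recipe: SROCC and KROCC on the raw
#' (objective, DMOS) pairs; a five-parameter logistic fit of objective
#' onto DMOS; PLCC, RMSE and MAE between the mapped scores and DMOS.
#'
#' @param objective metric scores (one per image).
#' @param dmos subjective scores, aligned with `objective`.
#' @return an `eval_report`: list with `srocc`, `krocc`, `plcc`,
#'   `rmse`, `mae`, `tau` (fitted logistic parameters), `n`.
#' @export
evaluate_metric <- function(objective, dmos) {
  q <- as.numeric(objective); s <- as.numeric(dmos)
  if (length(q) != length(s)) stop("input lengths differ", call. = FALSE)
  if (length(q) < 5L) stop("need at least 5 points", call. = FALSE)
  fit <- fit_logistic(q, s)
  mapped <- logistic_map(q, fit$tau)
  acc <- plcc_rmse_mae(mapped, s)
  structure(list(srocc = srocc(q, s), krocc = krocc(q, s),
                 plcc = acc$plcc, rmse = acc$rmse, mae = acc$mae,
                 tau = fit$tau, n = length(q)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> n = %d\n",
                     "  SROCC %7.4f  KROCC %7.4f  PLCC %7.4f\n",
                     "  RMSE  %7.4f  MAE   %7.4f\n"),
              x$n, x$srocc, x$krocc, x$plcc, x$rmse, x$mae))
  invisible(x)
}

#' MSE and PSNR baselines
#'
#' The benchmark pixel-statistics metrics, used as sanity anchors for
#' the harness (not as serious quality predictors).
#'
#' @param reference,distorted [image_plane()]s of equal size.
#' @return list with `mse` and `psnr` (dB; `Inf` for identical planes).
#' @export
baseline_scores <- function(reference, distorted) {
  reference <- as_image_plane(reference)
  distorted <- as_image_plane(distorted)
  check_same_dim(reference, distorted, "planes")
  mse <- mean((as_plain_matrix(reference) - as_plain_matrix(distorted))^2)
  dr <- dynamic_range(reference)
  psnr <- if (mse == 0) Inf else 10 * log10(dr^2 / mse)
  list(mse = mse, psnr = psnr)
}
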