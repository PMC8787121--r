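## Independent oracles: direct DFT summation, naive 2-D filtering with
## explicit index reflection, brute-force rank statistics. These
## deliberately avoid the package's vectorised/separable code paths
## (and stats::fft) so agreement is evidence, not tautology.

dft_matrix <- function(n) {
  idx <- 0:(n - 1)
  exp(-2i * pi * outer(idx, idx) / n)
}

## direct DFT by matrix summation (no FFT algorithm involved)
naive_dft2 <- function(m) {
  dft_matrix(nrow(m)) %*% m %*% dft_matrix(ncol(m))
}

naive_idft2 <- function(f) {
  (Conj(dft_matrix(nrow(f))) %*% f %*% Conj(dft_matrix(ncol(f)))) / length(f)
}

## symmetric reflection of an out-of-range index into [1, n]
reflect_idx <- function(i, n) {
  ifelse(i < 1L, 1L - i, ifelse(i > n, 2L * n + 1L - i, i))
}

## naive 2-D correlation with an arbitrary odd kernel, symmetric padding
naive_filter2d <- function(m, kern) {
  kh <- (nrow(kern) - 1L) %/% 2L
  kw <- (ncol(kern) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) {
    rr <- reflect_idx(r + (-kh:kh), nrow(m))
    for (cc in seq_len(ncol(m))) {
      ci <- reflect_idx(cc + (-kw:kw), ncol(m))
      out[r, cc] <- sum(kern * m[rr, ci])
    }
  }
  out
}

gauss_kernel_1d <- function(sigma, truncate = 4) {
  half <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- (-half):half
  w <- exp(-(x^2) / (2 * sigma^2))
  w / sum(w)
}

## full spectral-residual pipeline evaluated with the naive transforms
## (gamma = 1, no resize: feed it working-grid-sized images)
oracle_spectral_residual <- function(m, params) {
  f <- naive_dft2(m)
  a <- log(Mod(f) + params$log_epsilon)
  phase <- atan2(Im(f), Re(f))
  k <- params$residual_filter_size
  resid <- a - naive_filter2d(a, matrix(1 / k^2, k, k))
  sal <- Mod(naive_idft2(exp(resid + 1i * phase)))^2
  t1 <- gauss_kernel_1d(params$smooth_sigma)
  naive_filter2d(sal, outer(t1, t1))
}

## brute-force Spearman: ranks by pair counting, Pearson from sums
oracle_srocc <- function(a, b) {
  brute_rank <- function(x) {
    vapply(seq_along(x), function(i) {
      1 + sum(x < x[i]) + (sum(x == x[i]) - 1) / 2
    }, 0)
  }
  ra <- brute_rank(a); rb <- brute_rank(b)
  n <- length(a)
  num <- sum(ra * rb) - n * mean(ra) * mean(rb)
  den <- sqrt((sum(ra^2) - n * mean(ra)^2) * (sum(rb^2) - n * mean(rb)^2))
  num / den
}

## brute-force Kendall tau-b by explicit pair enumeration
oracle_krocc <- function(a, b) {
  n <- length(a)
  nc <- 0; nd <- 0; ta <- 0; tb <- 0; n0 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      n0 <- n0 + 1
      sa <- sign(a[j] - a[i]); sb <- sign(b[j] - b[i])
      if (sa == 0) ta <- ta + 1
      if (sb == 0) tb <- tb + 1
      if (sa != 0 && sb != 0) {
        if (sa == sb) nc <- nc + 1 else nd <- nd + 1
      }
    }
  }
  (nc - nd) / sqrt((n0 - ta) * (n0 - tb))
}

## per-pixel weighted moments by direct formula evaluation
oracle_local_moments <- function(m, taps) {
  k <- length(taps)
  kern <- outer(taps, taps)
  mu <- naive_filter2d(m, kern)
  ex2 <- naive_filter2d(m * m, kern)
  list(mean = mu, var = ex2 - mu^2)
}
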