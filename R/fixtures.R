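#' Specification of a synthetic pool-scene fixture
#'
#' The public pool-image database behind this metric is not deposited,
#' so tests and examples run on synthetic scenes that exercise the same
#' visual structure: quasi-periodic pool-tile texture (gradient
#' content), straight high-contrast lane/wall stripes (contour
#' saliency), compact bright elliptical blobs standing in for swimmers
#' (main targets), a smooth sinusoidal ripple warp (water refraction)
#' and additive sensor noise. Identical specs yield bit-identical
#' planes.
#'
#' @param seed integer RNG seed.
#' @param height,width image size in pixels (defaults 288 x 512, a
#'   16:9 frame at desk-test scale).
#' @param tile_period tile repeat length in pixels.
#' @param n_swimmers number of bright elliptical blobs.
#' @param ripple_amplitude sinusoidal warp amplitude in pixels.
#' @param noise_sd Gaussian noise standard deviation in pixel units.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, height = 288L, width = 512L,
                         tile_period = 32L, n_swimmers = 3L,
                         ripple_amplitude = 2, noise_sd = 2) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (height < 3 || width < 3) stop("height and width must be >= 3",
                                    call. = FALSE)
  if (tile_period < 2) stop("tile_period must be >= 2 pixels", call. = FALSE)
  if (n_swimmers < 0) stop("n_swimmers must be nonnegative", call. = FALSE)
  if (ripple_amplitude < 0 || noise_sd < 0) {
    stop("ripple_amplitude and noise_sd must be nonnegative", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), height = as.integer(height),
                 width = as.integer(width),
                 tile_period = as.integer(tile_period),
                 n_swimmers = as.integer(n_swimmers),
                 ripple_amplitude = ripple_amplitude, noise_sd = noise_sd),
            class = "fixture_spec")
}

## run `expr` under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic pool-scene fixture
#'
#' Deterministic composition (see [fixture_spec()]): tile grid, lane
#' stripes, swimmer blobs, ripple warp, sensor noise, clipped to
#' `[0, 255]` and quantised to integers (8-bit capture).
#'
#' @param spec a [fixture_spec()].
#' @return an [image_plane()].
#' @examples
#' img <- generate_pool_fixture(fixture_spec(seed = 7, height = 96, width = 128))
#' @export
generate_pool_fixture <- function(spec) {
  if (!inherits(spec, "fixture_spec")) spec <- do.call(fixture_spec, spec)
  h <- spec$height; w <- spec$width; tp <- spec$tile_period
  rows <- matrix(0:(h - 1), h, w)
  cols <- matrix(0:(w - 1), h, w, byrow = TRUE)

  with_seed(spec$seed, {
    ## (i) tile texture: checkerboard of half-period cells over a mid
    ## tone, with darker grout lines at tile boundaries; period tp in
    ## both directions
    half <- max(1L, tp %/% 2L)
    checker <- (floor(rows / half) + floor(cols / half)) %% 2
    base <- 150 + 40 * checker
    grout <- (rows %% tp == 0) | (cols %% tp == 0)
    base[grout] <- 90

    ## (ii) lane stripes: dark vertical bands with bright rims at fixed
    ## columns (constant down rows, so tile periodicity in r survives)
    lane_centres <- round(w * c(0.25, 0.5, 0.75))
    lane_halfw <- max(2L, round(w / 100))
    for (lc in lane_centres) {
      d <- abs(cols - lc)
      base[d <= lane_halfw] <- 25
      base[d > lane_halfw & d <= lane_halfw + 1] <- 230
    }

    ## (iii) swimmers: smooth bright elliptical Gaussian blobs at
    ## seeded positions/orientations
    if (spec$n_swimmers > 0L) {
      for (i in seq_len(spec$n_swimmers)) {
        cy <- runif(1, 0.15, 0.85) * h
        cx <- runif(1, 0.1, 0.9) * w
        a <- runif(1, 0.03, 0.06) * w   # semi-major, along body
        b <- a * runif(1, 0.35, 0.55)   # semi-minor
        ang <- runif(1, 0, pi)
        amp <- runif(1, 70, 100)
        u <- (cols - cx) * cos(ang) + (rows - cy) * sin(ang)
        v <- -(cols - cx) * sin(ang) + (rows - cy) * cos(ang)
        base <- base + amp * exp(-(u^2 / (2 * a^2) + v^2 / (2 * b^2)))
      }
    }

    ## (iv) ripple: smooth sinusoidal coordinate warp (water surface
    ## refraction), horizontal displacement varying with row
    if (spec$ripple_amplitude > 0) {
      lambda <- max(16, h / 3)
      phase <- runif(1, 0, 2 * pi)
      dx <- spec$ripple_amplitude * sin(2 * pi * rows / lambda + phase)
      dy <- 0.5 * spec$ripple_amplitude *
        sin(2 * pi * cols / (2 * lambda) + phase / 2)
      base <- sample_bilinear(base, rows + dy, cols + dx)
    }

    ## (v) sensor noise
    if (spec$noise_sd > 0) {
      base <- base + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
    }

    m <- pmin(pmax(round_half_up(base), 0), 255)
    image_plane(m, dynamic_range = 255)
  })
}
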