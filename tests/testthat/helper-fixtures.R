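## Shared fixture builders. Small sizes keep the default run fast; the
## acceptance suite uses the generator's stated defaults where the
## criterion depends on them.

small_fixture <- function(seed = 1L, height = 96L, width = 128L, ...) {
  generate_pool_fixture(fixture_spec(seed = seed, height = height,
                                     width = width, ...))
}

## seeded random image plane (uniform pixels)
random_plane <- function(seed, h, w, range = 255) {
  set.seed(seed)
  image_plane(matrix(round(runif(h * w, 0, range)), h, w),
              dynamic_range = range)
}

## parameters tuned for small test images: saliency at native scale
fast_params <- function(...) {
  mmiqa_params(saliency = saliency_params(working_width = 128L,
                                          smooth_sigma = 2),
               ...)
}

## the 3-point parameter grid used by identity/symmetry properties
params_grid <- function() {
  list(
    mmiqa_params(),
    mmiqa_params(w1 = 0.3, theta = 1.5, psi = 2,
                 window = window_spec("box", size = 9)),
    mmiqa_params(w1 = 1.2, psi = 0.5,
                 saliency = saliency_params(working_width = 192L,
                                            gamma = 1.2, smooth_sigma = 2))
  )
}

expect_python <- function() {
  ## codec-backed tests need python+Pillow; fail loudly if absent so a
  ## broken environment is never silently green
  expect_true(nzchar(Sys.which("python")) || nzchar(Sys.which("python3")))
}
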