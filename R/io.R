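#' Load an image as a grayscale plane
#'
#' Reads an 8-bit raster (PNG, JPEG, BMP, PGM or PPM). RGB input is
#' converted to luminance with the Rec. 601 weighting
#' `0.299 R + 0.587 G + 0.114 B`, rounded half-up to integers in
#' `[0, 255]` — the convention of the reference SSIM/FSIM
#' implementations. Grayscale input passes through unchanged.
#'
#' @param path path to an image file.
#' @return an [image_plane()] with `dynamic_range = 255`.
#' @export
load_image_gray <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pgm", "ppm", "pnm")) {
    dat <- read_pnm(path)
  } else {
    tmp <- tempfile(fileext = ".pnm")
    on.exit(unlink(tmp), add = TRUE)
    run_imtool(c("decode", shQuote(path), shQuote(tmp)))
    dat <- read_pnm(tmp)
  }
  if (is.list(dat)) {
    lum <- 0.299 * dat$r + 0.587 * dat$g + 0.114 * dat$b
    m <- pmin(pmax(round_half_up(lum), 0), 255)
    dim(m) <- dim(dat$r)
  } else {
    m <- dat
    attr(m, "maxval") <- NULL
  }
  storage.mode(m) <- "double"
  image_plane(m, dynamic_range = 255)
}

#' Write an image plane to disk
#'
#' PGM is written natively; PNG, BMP and JPEG go through the bundled
#' codec helper. Pixels are rounded half-up and clipped to `[0, 255]`.
#'
#' @param image an [image_plane()] (or numeric matrix).
#' @param path output path; the extension selects the format.
#' @param quality JPEG quality factor in `[1, 100]` (ignored for
#'   lossless formats).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, quality = 90) {
  m <- as_plain_matrix(as_image_plane(image))
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    write_pgm(m, path)
  } else if (ext %in% c("png", "bmp", "jpg", "jpeg")) {
    tmp <- tempfile(fileext = ".pgm")
    on.exit(unlink(tmp), add = TRUE)
    write_pgm(m, tmp)
    run_imtool(c("encode", shQuote(tmp), shQuote(path), as.character(quality)))
  } else {
    stop(sprintf("unsupported output format '.%s'", ext), call. = FALSE)
  }
  invisible(path)
}

#' JPEG-compress an image plane in memory
#'
#' Encodes the plane with a standard libjpeg-compatible codec at the
#' given quality factor and decodes it back, reproducing the distortion
#' applied when building a compression-quality database (quality ladder
#' 10, 20, 30, 40, 50).
#'
#' @param image an [image_plane()].
#' @param quality integer quality factor in `[1, 100]`; lower means
#'   stronger compression artifacts.
#' @return the decoded [image_plane()], same dimensions as the input.
#' @seealso [build_distortion_set()]
#' @export
jpeg_compress <- function(image, quality) {
  image <- as_image_plane(image)
  check_quality_levels(quality)
  jpeg_compress_multi(image, quality)[[1L]]
}

check_quality_levels <- function(levels) {
  if (length(levels) == 0L) stop("quality level list must be nonempty",
                                 call. = FALSE)
  if (anyNA(levels) || any(levels != as.integer(levels)) ||
      any(levels < 1) || any(levels > 100)) {
    stop("quality levels must be integers in [1, 100]", call. = FALSE)
  }
  if (anyDuplicated(levels)) stop("quality levels must be distinct",
                                  call. = FALSE)
  invisible(as.integer(levels))
}

## one helper invocation for a whole quality ladder (amortises process
## start-up when building distortion sets)
jpeg_compress_multi <- function(image, levels) {
  m <- as_plain_matrix(image)
  tdir <- tempfile("jpegrt")
  dir.create(tdir)
  on.exit(unlink(tdir, recursive = TRUE), add = TRUE)
  src <- file.path(tdir, "src.pgm")
  write_pgm(m, src)
  prefix <- file.path(tdir, "q")
  run_imtool(c("jpegrt", shQuote(src), shQuote(prefix),
               paste(as.integer(levels), collapse = ",")))
  lapply(levels, function(q) {
    out <- read_pnm(sprintf("%s%d.pgm", prefix, q))
    attr(out, "maxval") <- NULL
    storage.mode(out) <- "double"
    image_plane(out, dynamic_range = 255)
  })
}

#' Build a JPEG distortion set for one reference
#'
#' Produces one distorted plane per quality level, order preserved —
#' the unit of a compression-quality evaluation database (each
#' reference paired with its quality ladder, e.g. 10/20/30/40/50).
#'
#' @param reference an [image_plane()].
#' @param levels distinct integer JPEG quality factors in `[1, 100]`.
#' @param reference_id text label for the reference.
#' @return an object of class `distortion_set`: list with `reference_id`,
#'   `reference`, `levels`, `distorted` (list of planes, one per level).
#' @export
build_distortion_set <- function(reference, levels,
                                 reference_id = "reference") {
  reference <- as_image_plane(reference)
  levels <- check_quality_levels(levels)
  distorted <- jpeg_compress_multi(reference, levels)
  structure(list(reference_id = as.character(reference_id),
                 reference = reference,
                 levels = levels,
                 distorted = distorted),
            class = "distortion_set")
}

#' @export
print.distortion_set <- function(x, ...) {
  cat(sprintf("<distortion_set> '%s': %d x %d reference, levels {%s}\n",
              x$reference_id, nrow(x$reference), ncol(x$reference),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}
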