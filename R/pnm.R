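## Native reader/writer for binary PGM (P5) and PPM (P6), the
## interchange format between R and the bundled codec helper. 8-bit
## only; maxval > 255 is rejected as unsupported.

read_pnm_header <- function(con, path) {
  read_byte <- function() readBin(con, "raw", n = 1L)
  is_space <- function(b) b %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d, 0x0b, 0x0c))
  tokens <- character(0)
  repeat {
    b <- read_byte()
    if (length(b) == 0L) stop(sprintf("truncated PNM header in '%s'", path),
                              call. = FALSE)
    if (b == as.raw(0x23)) {  # '#' comment to end of line
      repeat {
        b <- read_byte()
        if (length(b) == 0L || b == as.raw(0x0a)) break
      }
    } else if (is_space(b)) {
      next
    } else {
      tok <- b
      repeat {
        b <- read_byte()
        if (length(b) == 0L || is_space(b)) break
        tok <- c(tok, b)
      }
      tokens <- c(tokens, rawToChar(tok))
      if (length(tokens) == 3L) break
    }
  }
  tokens
}

#' Read a binary PGM/PPM image
#'
#' @param path file path to a P5 (grayscale) or P6 (RGB) file.
#' @return for P5, an integer matrix; for P6, a 3-slot list of integer
#'   matrices `r`, `g`, `b`. Both carry attribute `maxval`.
#' @keywords internal
read_pnm <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                               call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P5", "P6")) {
    stop(sprintf("unsupported format: '%s' is not binary PGM/PPM", path),
         call. = FALSE)
  }
  hdr <- read_pnm_header(con, path)
  w <- as.integer(hdr[1]); h <- as.integer(hdr[2]); maxval <- as.integer(hdr[3])
  if (is.na(w) || is.na(h) || is.na(maxval)) {
    stop(sprintf("cannot decode '%s': malformed PNM header", path),
         call. = FALSE)
  }
  if (maxval > 255L) {
    stop(sprintf("unsupported format: '%s' has bit depth > 8", path),
         call. = FALSE)
  }
  nch <- if (magic == "P5") 1L else 3L
  n <- w * h * nch
  raw <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
  if (length(raw) < n) stop(sprintf("cannot decode '%s': truncated data", path),
                            call. = FALSE)
  if (nch == 1L) {
    m <- matrix(raw, nrow = h, ncol = w, byrow = TRUE)
    attr(m, "maxval") <- maxval
    m
  } else {
    a <- array(raw, dim = c(3L, w, h))
    out <- list(r = t(matrix(a[1, , ], w, h)),
                g = t(matrix(a[2, , ], w, h)),
                b = t(matrix(a[3, , ], w, h)))
    attr(out, "maxval") <- maxval
    out
  }
}

#' Write a binary PGM (grayscale) image
#'
#' @param m numeric matrix; values are rounded half-up and clipped to
#'   `[0, 255]`.
#' @param path output path.
#' @keywords internal
write_pgm <- function(m, path) {
  v <- pmin(pmax(round_half_up(as.vector(t(m))), 0), 255)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(m), nrow(m)), con,
            eos = NULL, useBytes = TRUE)
  writeBin(as.integer(v), con, size = 1L)
  invisible(path)
}

write_ppm <- function(r, g, b, path) {
  h <- nrow(r); w <- ncol(r)
  inter <- rbind(as.vector(t(r)), as.vector(t(g)), as.vector(t(b)))
  v <- pmin(pmax(round_half_up(as.vector(inter)), 0), 255)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL, useBytes = TRUE)
  writeBin(as.integer(v), con, size = 1L)
  invisible(path)
}
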