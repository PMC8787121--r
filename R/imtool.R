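## Bridge to the bundled Pillow codec helper (inst/python/imtool.py).
## Only byte-level encode/decode happens there; all pixel arithmetic is
## done in R.

imtool_path <- function() {
  p <- system.file("python", "imtool.py", package = "mmiqa")
  if (!nzchar(p)) stop("bundled codec helper not found; reinstall mmiqa",
                       call. = FALSE)
  p
}

python_binary <- function() {
  p <- Sys.getenv("MMIQA_PYTHON", "")
  if (nzchar(p)) return(p)
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) {
    stop("no `python` on PATH: PNG/JPEG/BMP support needs Python with Pillow",
         call. = FALSE)
  }
  p
}

run_imtool <- function(args) {
  out <- suppressWarnings(
    system2(python_binary(), c(shQuote(imtool_path()), args),
            stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop(paste(out, collapse = "\n"), call. = FALSE)
  }
  out
}
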