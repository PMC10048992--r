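# Minimal image I/O. The package standardizes on binary PPM (P6): a
# self-describing uncompressed format that needs no external decoder, is
# byte-for-byte reproducible, and round-trips exactly at 8-bit depth.
# All images in memory are H x W x 3 arrays in [0, 1].

#' Write / read a binary PPM image
#'
#' @param img `H x W x 3` numeric array in [0, 1] (clamped on write).
#' @param path file path (conventionally `.ppm`).
#' @return `fgr_write_ppm` returns `path` invisibly; `fgr_read_ppm` returns
#'   the image array.
#' @export
fgr_write_ppm <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3L] == 3L)
  H <- dim(img)[1L]; W <- dim(img)[2L]
  v <- round(pmin(pmax(img, 0), 1) * 255)
  # channel fastest, then column, then row = RGB triples in raster order
  bytes <- as.raw(as.integer(aperm(v, c(3L, 2L, 1L))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("P6\n%d %d\n255\n", W, H)), con)
  writeBin(bytes, con)
  invisible(path)
}

#' @rdname fgr_write_ppm
#' @export
fgr_read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    chars <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch)) break
      if (ch %in% c(" ", "\n", "\t", "\r")) {
        if (length(chars)) break else next
      }
      if (ch == "#") {  # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
        }
        if (length(chars)) break else next
      }
      chars <- c(chars, ch)
    }
    paste(chars, collapse = "")
  }
  magic <- tok()
  if (magic != "P6") stop("not a binary PPM (P6) file: ", path)
  W <- as.integer(tok()); H <- as.integer(tok()); maxv <- as.integer(tok())
  raw <- readBin(con, "raw", n = W * H * 3L)
  v <- as.integer(raw) / maxv
  aperm(array(v, c(3L, W, H)), c(3L, 2L, 1L))
}
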