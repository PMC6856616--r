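## Minimal baseline TIFF support (little-endian, uncompressed, grayscale,
## multi-page).  Written 32-bit float; the reader additionally accepts
## 8/16-bit unsigned integer pages.  Hand-rolled because no TIFF-capable R
## package is available in the target environment; intended for the
## simulator round trip and plain microscopy exports, not as a general
## TIFF implementation.

.TAG <- c(width = 256L, length = 257L, bps = 258L, compression = 259L,
          photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
          strip_bytes = 279L, sample_format = 339L)

#' Write matrices as a multi-page grayscale TIFF
#'
#' Pages are stored as uncompressed little-endian 32-bit IEEE floats.
#'
#' @param pages A matrix or list of equally-sized numeric matrices.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L, all(vapply(pages, is.matrix, logical(1))))
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(as.integer(x), con, size = size,
                                  endian = "little")
  writeChar("II", con, eos = NULL)
  w(42L, 2L)
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  data_bytes <- 4L * nx * ny
  n_entries <- length(.TAG)
  ifd_bytes <- 2L + n_entries * 12L + 4L
  ## layout: header(8) | page data ... | IFDs ...
  data_off <- 8L + (seq_along(pages) - 1L) * data_bytes
  ifd_off <- 8L + length(pages) * data_bytes +
    (seq_along(pages) - 1L) * ifd_bytes
  w(ifd_off[1L], 4L)
  for (p in seq_along(pages)) {
    writeBin(as.numeric(t(pages[[p]])), con, size = 4L, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    w(tag, 2L); w(type, 2L); w(count, 4L)
    if (type == 3L) { w(value, 2L); w(0L, 2L) } else w(value, 4L)
  }
  for (p in seq_along(pages)) {
    w(n_entries, 2L)
    entry(.TAG[["width"]], 4L, 1L, nx)
    entry(.TAG[["length"]], 4L, 1L, ny)
    entry(.TAG[["bps"]], 3L, 1L, 32L)
    entry(.TAG[["compression"]], 3L, 1L, 1L)
    entry(.TAG[["photometric"]], 3L, 1L, 1L)
    entry(.TAG[["strip_offsets"]], 4L, 1L, data_off[p])
    entry(.TAG[["rows_per_strip"]], 4L, 1L, ny)
    entry(.TAG[["strip_bytes"]], 4L, 1L, data_bytes)
    entry(.TAG[["sample_format"]], 3L, 1L, 3L)
    w(if (p < length(pages)) ifd_off[p + 1L] else 0L, 4L)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Supports uncompressed little- or big-endian single-sample pages with
#' 8/16-bit unsigned or 32-bit float data.
#'
#' @param path TIFF file.
#' @return List of numeric matrices, one per page.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8L) stop("read_tiff: truncated file", call. = FALSE)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
  else stop("read_tiff: not a TIFF (bad byte-order mark)", call. = FALSE)
  u <- function(off, size, n = 1L) {
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size == 4L)
  }
  if (u(2L, 2L) != 42L) stop("read_tiff: bad magic", call. = FALSE)
  ifd_off <- u(4L, 4L)
  pages <- list()
  while (ifd_off != 0L) {
    n <- u(ifd_off, 2L)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd_off + 2L + (k - 1L) * 12L
      tag <- u(e, 2L); type <- u(e + 2L, 2L); count <- u(e + 4L, 4L)
      val <- if (type == 3L && count == 1L) u(e + 8L, 2L) else u(e + 8L, 4L)
      if (count > 1L) {
        size <- c(1L, 1L, 2L, 4L)[min(type, 4L)]
        off <- u(e + 8L, 4L)
        val <- u(off, size, count)
      }
      tags[[as.character(tag)]] <- val
    }
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    nx <- g(256L); ny <- g(257L)
    bps <- g(258L, 1L)[1L]
    if (g(259L, 1L) != 1L) stop("read_tiff: compressed TIFF unsupported",
                                call. = FALSE)
    fmt <- g(339L, 1L)[1L]
    offs <- g(273L)
    byts <- g(279L)
    bytes_px <- bps %/% 8L
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      npix <- byts[s] %/% bytes_px
      seg <- raw[(offs[s] + 1L):(offs[s] + byts[s])]
      vals <- c(vals, if (fmt == 3L) {
        readBin(seg, "double", n = npix, size = bytes_px, endian = endian)
      } else {
        v <- readBin(seg, "integer", n = npix, size = bytes_px,
                     endian = endian, signed = bytes_px == 4L)
        if (bytes_px == 4L) v[v < 0] <- v[v < 0] + 2^32
        v
      })
    }
    if (length(vals) != nx * ny) {
      stop("read_tiff: pixel count mismatch", call. = FALSE)
    }
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = ny, ncol = nx,
                                          byrow = TRUE)
    ifd_off <- u(ifd_off + 2L + n * 12L, 4L)
  }
  pages
}
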