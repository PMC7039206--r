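# Minimal baseline TIFF codec: uncompressed little-endian grayscale,
# 8/16-bit unsigned or 32-bit float, single- or multi-page. The
# pre-installed R stack has no TIFF package, and image stacks here are
# small synthetic patches, so a strict baseline subset is implemented
# rather than depending on one that cannot be installed offline.

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L,
               sample_format = 339L)

# type sizes for TIFF field types 1..12 (we only use/accept 1,3,4,11)
tiff_type_size <- function(type) {
  c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)[type]
}

#' Write an image or stack as an uncompressed grayscale TIFF
#'
#' Integer data in `[0, 65535]` is stored as 16-bit unsigned; anything
#' else as 32-bit float. One page per frame for 3D input.
#'
#' @param x numeric matrix `[y, x]` or 3D array `[y, x, t]`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_tiff <- function(x, path) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 3L) stop("x must be a matrix or 3D array",
                                 call. = FALSE)
  h <- dim(x)[1L]; w <- dim(x)[2L]; n <- dim(x)[3L]
  vals <- as.vector(x)
  as_int <- all(is.finite(vals)) && all(vals == round(vals)) &&
    all(vals >= 0) && all(vals <= 65535)
  bytes_pp <- if (as_int) 2L else 4L
  fmt <- if (as_int) 1L else 3L  # 1 = unsigned int, 3 = IEEE float
  strip_bytes <- h * w * bytes_pp
  ifd_size <- 2L + 10L * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  # layout per page: [strip data][IFD]; first IFD offset follows page 1 data
  data_off <- 8L
  ifd_off <- data_off + strip_bytes
  writeBin(as.integer(ifd_off), con, size = 4L, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (type == 3L) {
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  for (p in seq_len(n)) {
    # pixel data, row-major (TIFF scanline order)
    page <- t(x[, , p])
    if (as_int) {
      writeBin(as.integer(page), con, size = 2L, endian = "little")
    } else {
      writeBin(as.numeric(page), con, size = 4L, endian = "little")
    }
    next_ifd <- if (p < n) ifd_off + ifd_size + strip_bytes else 0L
    writeBin(10L, con, size = 2L, endian = "little")  # entry count
    entry(256L, 4L, 1L, w)
    entry(257L, 4L, 1L, h)
    entry(258L, 3L, 1L, bytes_pp * 8L)
    entry(259L, 3L, 1L, 1L)          # no compression
    entry(262L, 3L, 1L, 1L)          # BlackIsZero
    entry(273L, 4L, 1L, data_off)    # single strip
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, h)
    entry(279L, 4L, 1L, strip_bytes)
    entry(339L, 3L, 1L, fmt)
    writeBin(as.integer(next_ifd), con, size = 4L, endian = "little")
    data_off <- ifd_off + ifd_size
    ifd_off <- data_off + strip_bytes
  }
  invisible(path)
}

#' Read an uncompressed grayscale TIFF into an image stack
#'
#' Supports the baseline subset written by [write_tiff()] plus common
#' plain exports: little- or big-endian, 8/16-bit unsigned or 32-bit
#' float, one sample per pixel, any strip layout, no compression.
#'
#' @param path TIFF file.
#' @return an [image_stack()] array `[y, x, frame]`.
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  con <- rawConnection(raw)
  on.exit(close(con))
  endian <- rawToChar(raw[1:2])
  endian <- switch(endian, II = "little", MM = "big",
                   stop("not a TIFF file: ", path, call. = FALSE))
  rd <- function(off, n, size, what = "integer") {
    seek(con, off)
    # signed=FALSE is only valid for 1/2-byte ints; 4-byte offsets in the
    # small files handled here never exceed .Machine$integer.max
    readBin(con, what, n = n, size = size, endian = endian,
            signed = !(what == "integer" && size <= 2))
  }
  magic <- rd(2, 1, 2)
  if (magic != 42L) stop("not a TIFF file: ", path, call. = FALSE)
  ifd_off <- rd(4, 1, 4)
  frames <- list()
  while (ifd_off != 0) {
    n_entries <- rd(ifd_off, 1, 2)
    tags <- list()
    for (e in seq_len(n_entries)) {
      eo <- ifd_off + 2 + (e - 1) * 12
      tag <- rd(eo, 1, 2)
      type <- rd(eo + 2, 1, 2)
      count <- rd(eo + 4, 1, 4)
      size <- tiff_type_size(type)
      total <- size * count
      voff <- if (total <= 4) eo + 8 else rd(eo + 8, 1, 4)
      vals <- if (type == 11L) {
        rd(voff, count, 4, what = "numeric")
      } else {
        rd(voff, count, size)
      }
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    w <- g(256L); h <- g(257L)
    if (is.null(w) || is.null(h)) stop("TIFF IFD missing dimensions",
                                       call. = FALSE)
    bits <- g(258L, 1L)[1L]
    if (g(259L, 1L) != 1L) stop("compressed TIFF not supported",
                                call. = FALSE)
    if (g(277L, 1L) != 1L) stop("multi-sample TIFF not supported",
                                call. = FALSE)
    fmt <- g(339L, 1L)[1L]
    offs <- g(273L)
    cnts <- g(279L, h * w * bits / 8)
    bpp <- bits / 8
    px <- numeric(0)
    for (s in seq_along(offs)) {
      n_px <- cnts[s] / bpp
      px <- c(px, if (fmt == 3L) {
        rd(offs[s], n_px, bpp, what = "numeric")
      } else {
        rd(offs[s], n_px, bpp)
      })
    }
    if (length(px) < w * h) stop("truncated TIFF strip data", call. = FALSE)
    frames[[length(frames) + 1L]] <- t(matrix(px[seq_len(w * h)],
                                              nrow = w, ncol = h))
    ifd_off <- rd(ifd_off + 2 + n_entries * 12, 1, 4)
  }
  stack <- array(0, dim = c(nrow(frames[[1L]]), ncol(frames[[1L]]),
                            length(frames)))
  for (i in seq_along(frames)) stack[, , i] <- frames[[i]]
  image_stack(stack)
}
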