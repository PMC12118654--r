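## Minimal baseline TIFF codec: multi-page, single-sample grayscale,
## uncompressed. Written because no TIFF package is available in the target
## R stack. Supports reading II/MM byte order, 8/16/32-bit unsigned integer
## and 32-bit float samples, any strip layout; writes little-endian with one
## strip per page. Sufficient for channel stacks and label masks; not a
## general TIFF library (no compression, tiles, palettes or RGB).

.tif_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                    `11` = 4L, `12` = 8L)

.rd_uint <- function(raw, offset, size, little) {
  ## offset is 0-based
  b <- as.integer(raw[offset + seq_len(size)])
  if (!little) b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

.rd_tag_values <- function(raw, entry_off, little) {
  type <- .rd_uint(raw, entry_off + 2, 2, little)
  count <- .rd_uint(raw, entry_off + 4, 4, little)
  sz <- .tif_type_size[[as.character(type)]]
  total <- sz * count
  voff <- if (total <= 4) entry_off + 8 else .rd_uint(raw, entry_off + 8, 4, little)
  endian <- if (little) "little" else "big"
  bytes <- raw[voff + seq_len(total)]
  if (type %in% c(3, 4, 1)) {
    vapply(seq_len(count) - 1L, function(i) .rd_uint(bytes, i * sz, sz, little), 0)
  } else if (type == 11) {
    readBin(bytes, "double", n = count, size = 4L, endian = endian)
  } else {
    stop("unsupported TIFF tag type: ", type)
  }
}

#' Read a multi-page grayscale TIFF as a list of matrices
#'
#' @param path file path.
#' @return list of numeric matrices, one per page (row 1 = top scanline).
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  order_tag <- rawToChar(raw[1:2])
  little <- identical(order_tag, "II")
  if (!little && !identical(order_tag, "MM")) stop("not a TIFF file: ", path)
  if (.rd_uint(raw, 2, 2, little) != 42) stop("not a TIFF file: ", path)
  endian <- if (little) "little" else "big"
  ifd <- .rd_uint(raw, 4, 4, little)
  pages <- list()
  while (ifd != 0) {
    ntag <- .rd_uint(raw, ifd, 2, little)
    tags <- list()
    for (k in seq_len(ntag) - 1L) {
      eoff <- ifd + 2 + 12 * k
      id <- .rd_uint(raw, eoff, 2, little)
      if (id %in% c(256, 257, 258, 259, 262, 273, 277, 278, 279, 339)) {
        tags[[as.character(id)]] <- .rd_tag_values(raw, eoff, little)
      }
    }
    need <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF page missing required tag ", id)
        default
      } else v
    }
    width <- need(256); height <- need(257)
    bits <- need(258, 1)[1]
    if (need(259, 1)[1] != 1) stop("compressed TIFF not supported")
    if (need(277, 1)[1] != 1) stop("multi-sample TIFF not supported")
    sfmt <- need(339, 1)[1]
    offsets <- need(273); counts <- need(279)
    buf <- raw(sum(counts))
    pos <- 0L
    for (s in seq_along(offsets)) {
      buf[pos + seq_len(counts[s])] <- raw[offsets[s] + seq_len(counts[s])]
      pos <- pos + counts[s]
    }
    n <- width * height
    vals <- if (sfmt == 3) {
      if (bits != 32) stop("only 32-bit float TIFF supported")
      readBin(buf, "double", n = n, size = 4L, endian = endian)
    } else if (bits == 8) {
      as.numeric(readBin(buf, "integer", n = n, size = 1L, signed = FALSE))
    } else if (bits == 16) {
      as.numeric(readBin(buf, "integer", n = n, size = 2L, signed = FALSE,
                         endian = endian))
    } else if (bits == 32) {
      v <- readBin(buf, "integer", n = n, size = 4L, endian = endian)
      ifelse(v < 0, v + 2^32, as.numeric(v))
    } else stop("unsupported bit depth: ", bits)
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = height, ncol = width,
                                          byrow = TRUE)
    ifd <- .rd_uint(raw, ifd + 2 + 12 * ntag, 4, little)
  }
  pages
}

.wr_entry <- function(con, id, type, count, value) {
  writeBin(as.integer(id), con, size = 2L, endian = "little")
  writeBin(as.integer(type), con, size = 2L, endian = "little")
  writeBin(as.integer(count), con, size = 4L, endian = "little")
  if (type == 3) {   # SHORT, inline left-justified
    writeBin(as.integer(value), con, size = 2L, endian = "little")
    writeBin(0L, con, size = 2L, endian = "little")
  } else {           # LONG
    writeBin(as.integer(value), con, size = 4L, endian = "little")
  }
}

#' Write matrices as a multi-page grayscale TIFF
#'
#' Pages are written uncompressed, little-endian, one strip per page.
#' `format = "float"` stores 32-bit IEEE floats (intensity channels);
#' `format = "uint"` stores unsigned integers, choosing 16 or 32 bits from
#' the largest value present (label masks).
#'
#' @param pages matrix or list of matrices, identical shapes not required.
#' @param path output file path.
#' @param format "float" or "uint".
#' @export
write_tiff_stack <- function(pages, path, format = c("float", "uint")) {
  format <- match.arg(format)
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1, all(vapply(pages, is.matrix, TRUE)))
  if (format == "uint") {
    mx <- max(0, vapply(pages, max, 0))
    if (any(vapply(pages, function(p) any(p < 0 | p != floor(p)), TRUE)))
      stop("uint TIFF requires nonnegative integer values")
    if (mx > 2^31 - 1) stop("label overflow: values exceed 32-bit range")
    bits <- if (mx > 65535) 32L else 16L
  } else bits <- 32L
  bpp <- bits %/% 8L
  n_ifd_entries <- 10L
  ifd_size <- 2L + 12L * n_ifd_entries + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2L, endian = "little")
  data_sizes <- vapply(pages, function(p) length(p) * bpp, 0)
  ## layout: header | page1 data | page1 IFD | page2 data | page2 IFD | ...
  first_ifd <- 8L + data_sizes[1]
  writeBin(as.integer(first_ifd), con, size = 4L, endian = "little")
  pos <- 8
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    v <- as.vector(t(p))   # scanline (row-major) order
    if (format == "float") {
      writeBin(v, con, size = 4L, endian = "little")
    } else if (bits == 16L) {
      writeBin(as.integer(v), con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(v), con, size = 4L, endian = "little")
    }
    data_off <- pos
    ifd_off <- pos + data_sizes[i]
    next_ifd <- if (i < length(pages)) ifd_off + ifd_size + data_sizes[i + 1] else 0
    writeBin(n_ifd_entries, con, size = 2L, endian = "little")
    .wr_entry(con, 256, 4, 1, ncol(p))
    .wr_entry(con, 257, 4, 1, nrow(p))
    .wr_entry(con, 258, 3, 1, bits)
    .wr_entry(con, 259, 3, 1, 1)              # no compression
    .wr_entry(con, 262, 3, 1, 1)              # black is zero
    .wr_entry(con, 273, 4, 1, data_off)
    .wr_entry(con, 277, 3, 1, 1)
    .wr_entry(con, 278, 4, 1, nrow(p))
    .wr_entry(con, 279, 4, 1, data_sizes[i])
    .wr_entry(con, 339, 3, 1, if (format == "float") 3 else 1)
    writeBin(as.integer(next_ifd), con, size = 4L, endian = "little")
    pos <- ifd_off + ifd_size
  }
  invisible(path)
}
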