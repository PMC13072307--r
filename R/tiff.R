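# Minimal baseline TIFF support: multi-page, uncompressed, single-channel
# grayscale, 8- or 16-bit. One strip per page on write; multi-strip and both
# byte orders accepted on read. Pages are B-scans: rows = depth z, cols = x.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, samples = 277L,
               rows_per_strip = 278L, strip_bytes = 279L)

write_tiff_pages <- function(pages, path, bits) {
  stopifnot(bits %in% c(8L, 16L))
  con <- file(path, "wb")
  on.exit(close(con))
  endian <- "little"
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = endian)
  n_pages <- length(pages)
  bytes_px <- bits / 8L
  nzs <- vapply(pages, nrow, integer(1))
  nxs <- vapply(pages, ncol, integer(1))
  page_bytes <- nzs * nxs * bytes_px
  padded <- page_bytes + page_bytes %% 2L
  offsets <- 8L + cumsum(c(0L, padded[-n_pages]))
  n_tags <- 9L
  ifd_size <- 2L + n_tags * 12L + 4L
  ifd_start <- 8L + sum(padded)
  writeBin(as.integer(ifd_start), con, size = 4, endian = endian)

  for (p in seq_len(n_pages)) {
    v <- as.integer(t(pages[[p]]))  # scanline order: z rows of nx pixels
    writeBin(v, con, size = bytes_px, endian = endian)
    if (page_bytes[p] %% 2L) writeBin(as.raw(0L), con)
  }

  write_tag <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = endian)
    writeBin(as.integer(type), con, size = 2, endian = endian)
    writeBin(as.integer(count), con, size = 4, endian = endian)
    if (type == 3L) {  # SHORT: left-justified in the 4-byte value field
      writeBin(as.integer(value), con, size = 2, endian = endian)
      writeBin(0L, con, size = 2, endian = endian)
    } else {
      writeBin(as.integer(value), con, size = 4, endian = endian)
    }
  }

  for (p in seq_len(n_pages)) {
    writeBin(as.integer(n_tags), con, size = 2, endian = endian)
    write_tag(256L, 3L, 1L, nxs[p])
    write_tag(257L, 3L, 1L, nzs[p])
    write_tag(258L, 3L, 1L, bits)
    write_tag(259L, 3L, 1L, 1L)   # no compression
    write_tag(262L, 3L, 1L, 1L)   # BlackIsZero
    write_tag(273L, 4L, 1L, offsets[p])
    write_tag(277L, 3L, 1L, 1L)
    write_tag(278L, 3L, 1L, nzs[p])
    write_tag(279L, 4L, 1L, page_bytes[p])
    next_ifd <- if (p < n_pages) ifd_start + p * ifd_size else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = endian)
  }
  invisible(path)
}

read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop_ovm("'%s' is not a TIFF file (too short)", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop_ovm("'%s' is not a TIFF file (bad byte-order mark)", path))
  u16 <- function(at) readBin(raw[at + 0:1], "integer", size = 2,
                              endian = endian, signed = FALSE)
  u32 <- function(at) readBin(raw[at + 0:3], "integer", size = 4, endian = endian)
  if (u16(3L) != 42L) stop_ovm("'%s' is not a TIFF file (bad magic)", path)

  read_tag_values <- function(entry_at) {
    type <- u16(entry_at + 2L)
    count <- u32(entry_at + 4L)
    # only integer-valued tag types matter here; others (ASCII, RATIONAL,
    # ...) belong to tags this reader ignores
    size <- switch(as.character(type), `1` = 1L, `3` = 2L, `4` = 4L,
                   return(NULL))
    total <- size * count
    at <- if (total <= 4L) entry_at + 8L else u32(entry_at + 8L) + 1L
    readBin(raw[at + seq_len(total) - 1L], "integer", n = count, size = size,
            endian = endian, signed = size >= 4L)
  }

  pages <- list()
  ifd_at <- u32(5L) + 1L
  page_no <- 0L
  while (ifd_at > 1L) {
    page_no <- page_no + 1L
    n_tags <- u16(ifd_at)
    tags <- list()
    for (i in seq_len(n_tags)) {
      entry_at <- ifd_at + 2L + (i - 1L) * 12L
      tags[[as.character(u16(entry_at))]] <- read_tag_values(entry_at)
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    nx <- g(256L); nz <- g(257L)
    if (is.null(nx) || is.null(nz))
      stop_ovm("TIFF page %d lacks image dimensions", page_no)
    bits <- g(258L, 1L)[1]
    if (!bits %in% c(8L, 16L))
      stop_ovm("TIFF page %d: only 8- and 16-bit grayscale supported (got %d bits)",
               page_no, bits)
    if (g(259L, 1L) != 1L)
      stop_ovm("TIFF page %d is compressed; only uncompressed TIFF is supported",
               page_no)
    if (g(277L, 1L) != 1L)
      stop_ovm("TIFF page %d has multiple samples per pixel; grayscale required",
               page_no)
    offs <- g(273L); byts <- g(279L)
    if (is.null(offs)) stop_ovm("TIFF page %d lacks strip offsets", page_no)
    if (is.null(byts)) byts <- rep(nx * nz * bits / 8L / length(offs), length(offs))
    px <- integer(0)
    for (s in seq_along(offs)) {
      at <- offs[s] + 1L
      px <- c(px, readBin(raw[at + seq_len(byts[s]) - 1L], "integer",
                          n = byts[s] / (bits / 8L), size = bits / 8L,
                          endian = endian, signed = FALSE))
    }
    if (length(px) != nx * nz)
      stop_ovm("TIFF page %d: strip data does not match %d x %d pixels",
               page_no, nz, nx)
    pages[[page_no]] <- matrix(px, nrow = nz, ncol = nx, byrow = TRUE)
    ifd_at <- u32(ifd_at + 2L + n_tags * 12L) + 1L
  }
  if (!length(pages)) stop_ovm("'%s' contains no TIFF pages", path)
  dims <- vapply(pages, dim, integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad))
    stop_ovm("TIFF pages have inconsistent sizes: page %d is %d x %d, expected %d x %d",
             bad[1], dims[1, bad[1]], dims[2, bad[1]], dims[1, 1], dims[2, 1])
  pages
}
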