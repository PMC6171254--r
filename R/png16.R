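# Minimal 16-bit grayscale PNG writer. The png package reads 16-bit images
# but writes only 8-bit, which would quantize color-difference heatmaps; the
# PNG container (IHDR/IDAT/IEND + zlib via memCompress + CRC-32) is simple
# enough to emit directly.

# CRC-32 (polynomial 0xEDB88320) on little-endian byte quadruples
crc32_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(crc32_env$table)) return(crc32_env$table)
  poly <- c(0x20L, 0x83L, 0xB8L, 0xEDL)  # LSB-first bytes of the polynomial
  tab <- matrix(0L, 256L, 4L)
  for (n in 0:255) {
    b <- c(n, 0L, 0L, 0L)
    for (k in 1:8) {
      lsb <- bitwAnd(b[1L], 1L)
      # shift the 32-bit value right by one across the four bytes
      b <- c(bitwOr(bitwShiftR(b[1L], 1L),
                    bitwShiftL(bitwAnd(b[2L], 1L), 7L)),
             bitwOr(bitwShiftR(b[2L], 1L),
                    bitwShiftL(bitwAnd(b[3L], 1L), 7L)),
             bitwOr(bitwShiftR(b[3L], 1L),
                    bitwShiftL(bitwAnd(b[4L], 1L), 7L)),
             bitwShiftR(b[4L], 1L))
      if (lsb == 1L) b <- bitwXor(b, poly)
    }
    tab[n + 1L, ] <- b
  }
  crc32_env$table <- tab
  tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- rep(255L, 4L)
  for (v in as.integer(bytes)) {
    idx <- bitwXor(crc[1L], v)
    crc <- bitwXor(c(crc[2L], crc[3L], crc[4L], 0L), tab[idx + 1L, ])
  }
  crc <- bitwXor(crc, 255L)
  rev(crc)  # big-endian byte order for the PNG chunk field
}

be32 <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256,
           x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(be32(length(data)), body, as.raw(crc32(body)))
}

#' Write a matrix as a 16-bit grayscale PNG
#'
#' Values must lie in \[0, 1\]; they are stored as 16-bit samples
#' (`round(v * 65535)`).
#'
#' @param m numeric matrix (rows = image rows).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_png16 <- function(m, file) {
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop("values must be finite and in [0, 1]")
  h <- nrow(m); w <- ncol(m)
  codes <- round(t(m) * 65535)           # row-major scanlines
  hi <- as.integer(codes %/% 256); lo <- as.integer(codes %% 256)
  row_bytes <- matrix(0L, 2L * w, h)
  row_bytes[seq(1L, 2L * w, by = 2L), ] <- hi
  row_bytes[seq(2L, 2L * w, by = 2L), ] <- lo
  scan <- as.raw(rbind(0L, row_bytes))   # leading filter byte per scanline
  ihdr <- c(be32(w), be32(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(scan, "gzip")),
           png_chunk("IEND", raw(0)))
  writeBin(out, file)
  invisible(file)
}
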