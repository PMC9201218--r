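# Minimal pure-R PNG codec (grayscale focus).  No pre-installed R
# package in this stack reads or writes PNG, so the container format is
# implemented here directly: chunk framing with CRC-32, zlib streams
# through memCompress/memDecompress, and the five scanline filters.
# Supported on read: bit depths 8/16, color types 0 (gray) and 2 (RGB),
# non-interlaced.  Written files are 8-bit grayscale, filter 0.

png_sig <- as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))

# CRC-32 table kept as four byte-planes so the update loop only needs
# 8-bit xors (R's bitw* operators are safe there).
crc_table_bytes <- local({
  b0 <- 0:255; b1 <- b2 <- b3 <- rep(0L, 256)
  poly <- c(0x20L, 0x83L, 0xB8L, 0xEDL)  # 0xEDB88320, LSB first
  for (k in 1:8) {
    bit <- b0 %% 2L
    b0 <- b0 %/% 2L + (b1 %% 2L) * 128L
    b1 <- b1 %/% 2L + (b2 %% 2L) * 128L
    b2 <- b2 %/% 2L + (b3 %% 2L) * 128L
    b3 <- b3 %/% 2L
    hit <- bit == 1L
    b0[hit] <- bitwXor(b0[hit], poly[1L])
    b1[hit] <- bitwXor(b1[hit], poly[2L])
    b2[hit] <- bitwXor(b2[hit], poly[3L])
    b3[hit] <- bitwXor(b3[hit], poly[4L])
  }
  cbind(b0, b1, b2, b3)
})

crc32_bytes <- function(bytes) {
  c0 <- c1 <- c2 <- c3 <- 255L
  tb <- crc_table_bytes
  for (by in bytes) {
    idx <- bitwXor(c0, by) + 1L
    c0 <- bitwXor(tb[idx, 1L], c1)
    c1 <- bitwXor(tb[idx, 2L], c2)
    c2 <- bitwXor(tb[idx, 3L], c3)
    c3 <- tb[idx, 4L]
  }
  c(bitwXor(c3, 255L), bitwXor(c2, 255L), bitwXor(c1, 255L), bitwXor(c0, 255L))
}

uint32_be <- function(x) {
  as.raw(c(x %/% 16777216 %% 256, x %/% 65536 %% 256, x %/% 256 %% 256, x %% 256))
}

be_uint <- function(bytes) sum(as.integer(bytes) * 256^((length(bytes) - 1):0))

png_chunk <- function(type, data) {
  tb <- c(as.integer(charToRaw(type)), as.integer(data))
  c(uint32_be(length(data)), charToRaw(type), data, as.raw(crc32_bytes(tb)))
}

#' Write an 8-bit grayscale PNG
#'
#' Intensities are rounded and clipped to `[0, 255]`.
#'
#' @param image numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(image, path) {
  H <- nrow(image); W <- ncol(image)
  px <- as.integer(round(clamp(image, 0, 255)))
  # scanlines: filter byte 0, then the row left to right
  sl <- rbind(0L, t(matrix(px, H, W)))
  raw_data <- as.raw(as.vector(sl))
  ihdr <- c(uint32_be(W), uint32_be(H), as.raw(c(8L, 0L, 0L, 0L, 0L)))
  idat <- memCompress(raw_data, type = "gzip")   # zlib stream (0x78 header)
  out <- c(png_sig,
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

paeth_predict <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  if (pa <= pb && pa <= pc) a else if (pb <= pc) b else c
}

unfilter_scanlines <- function(data, H, W, bpp) {
  stride <- W * bpp
  out <- matrix(0L, H, stride)
  prev <- rep(0L, stride)
  pos <- 1L
  for (r in seq_len(H)) {
    ft <- as.integer(data[pos])
    rb <- as.integer(data[pos + seq_len(stride)])
    pos <- pos + stride + 1L
    rec <- switch(as.character(ft),
      "0" = rb,
      "1" = {
        rec <- rb
        for (k in seq_len(bpp)) {
          idx <- seq.int(k, stride, bpp)
          rec[idx] <- cumsum(rb[idx]) %% 256L
        }
        rec
      },
      "2" = (rb + prev) %% 256L,
      "3" = {
        rec <- integer(stride)
        for (i in seq_len(stride)) {
          left <- if (i > bpp) rec[i - bpp] else 0L
          rec[i] <- (rb[i] + (left + prev[i]) %/% 2L) %% 256L
        }
        rec
      },
      "4" = {
        rec <- integer(stride)
        for (i in seq_len(stride)) {
          left <- if (i > bpp) rec[i - bpp] else 0L
          upl <- if (i > bpp) prev[i - bpp] else 0L
          rec[i] <- (rb[i] + paeth_predict(left, prev[i], upl)) %% 256L
        }
        rec
      },
      stop(sprintf("unsupported PNG filter type %d", ft)))
    out[r, ] <- rec
    prev <- rec
  }
  out
}

#' Read a PNG file as a grayscale image
#'
#' Supports non-interlaced 8- and 16-bit grayscale and RGB PNGs.  RGB is
#' converted by Rec. 601 luminance; 16-bit samples are rescaled linearly
#' to `[0, 255]`.
#'
#' @param path PNG file path.
#' @return numeric matrix with intensities in `[0, 255]`.
#' @export
read_png <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 8 || !identical(bytes[1:8], png_sig))
    stop(sprintf("'%s' is not a PNG file", path))
  pos <- 9L
  idat <- list(); meta <- NULL
  while (pos + 8 <= length(bytes)) {
    len <- be_uint(bytes[pos:(pos + 3L)])
    type <- rawToChar(bytes[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) bytes[(pos + 8L):(pos + 7L + len)] else raw(0)
    pos <- pos + 12L + len
    if (type == "IHDR") {
      meta <- list(W = be_uint(data[1:4]), H = be_uint(data[5:8]),
                   depth = as.integer(data[9]), color = as.integer(data[10]),
                   interlace = as.integer(data[13]))
    } else if (type == "IDAT") {
      idat[[length(idat) + 1L]] <- data
    } else if (type == "IEND") break
  }
  if (is.null(meta)) stop("PNG has no IHDR chunk")
  if (meta$interlace != 0L) stop("interlaced PNG is not supported")
  if (!meta$color %in% c(0L, 2L) || !meta$depth %in% c(8L, 16L))
    stop(sprintf("unsupported PNG layout (color type %d, bit depth %d); use 8/16-bit grayscale or RGB",
                 meta$color, meta$depth))
  channels <- if (meta$color == 0L) 1L else 3L
  bps <- meta$depth %/% 8L
  bpp <- channels * bps
  data <- memDecompress(do.call(c, idat), type = "gzip")
  rows <- unfilter_scanlines(data, meta$H, meta$W, bpp)
  # rows: H x (W*bpp) byte matrix -> numeric samples H x W x channels
  sample_at <- function(ch) {
    off <- (ch - 1L) * bps
    if (bps == 1L) rows[, off + seq.int(1L, meta$W * bpp, bpp), drop = FALSE]
    else {
      hi <- rows[, off + seq.int(1L, meta$W * bpp, bpp), drop = FALSE]
      lo <- rows[, off + seq.int(2L, meta$W * bpp, bpp), drop = FALSE]
      (hi * 256 + lo) * (255 / 65535)
    }
  }
  img <- if (channels == 1L) sample_at(1L)
         else 0.299 * sample_at(1L) + 0.587 * sample_at(2L) + 0.114 * sample_at(3L)
  matrix(as.numeric(img), meta$H, meta$W)
}
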