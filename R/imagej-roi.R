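# Minimal ImageJ .roi codec (polygon ROIs only) and a stored-entry ZIP
# container writer. The .roi format is a fixed 64-byte big-endian header
# ("Iout", version, type, bounding box, vertex count) followed by the x then
# y vertex arrays as 16-bit integers relative to the bounding box corner.
# ROI sets are shipped as a plain ZIP archive of .roi entries; entries are
# written uncompressed (method "store") so no compressor is needed.

ROI_TYPE_POLYGON <- 0L

encode_imagej_roi <- function(vertices) {
  v <- close_polygon(vertices)
  if (any(abs(v - round(v)) > 1e-9)) {
    warn("ImageJ ROI stores integer pixel coordinates; vertices were rounded.")
  }
  v <- round(v)
  left <- min(v[, 1]); top <- min(v[, 2])
  right <- max(v[, 1]); bottom <- max(v[, 2])
  n <- nrow(v)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeChar("Iout", con, 4, eos = NULL)
  writeBin(227L, con, size = 2, endian = "big")            # version
  writeBin(as.integer(c(ROI_TYPE_POLYGON, 0L)), con, size = 1)  # type + pad
  writeBin(as.integer(c(top, left, bottom, right, n)), con,
           size = 2, endian = "big")
  writeBin(raw(64 - 18), con)                               # unused header tail
  writeBin(as.integer(v[, 1] - left), con, size = 2, endian = "big")
  writeBin(as.integer(v[, 2] - top), con, size = 2, endian = "big")
  rawConnectionValue(con)
}

decode_imagej_roi <- function(bytes) {
  if (length(bytes) < 64 || rawToChar(bytes[1:4]) != "Iout") {
    abort("Not an ImageJ ROI (missing 'Iout' magic).")
  }
  rd_i2 <- function(off, n = 1, signed = TRUE) {
    readBin(bytes[(off + 1):(off + 2 * n)], "integer", n = n, size = 2,
            endian = "big", signed = signed)
  }
  type <- as.integer(bytes[7])
  if (type != ROI_TYPE_POLYGON) {
    abort(sprintf("Unsupported ROI type %d; only polygon ROIs are read.", type))
  }
  top <- rd_i2(8); left <- rd_i2(10)
  n <- rd_i2(16, signed = FALSE)
  xs <- rd_i2(64, n)
  ys <- rd_i2(64 + 2 * n, n)
  cbind(x = as.double(left + xs), y = as.double(top + ys))
}

# -- CRC-32 (IEEE 802.3), table-driven, on R's 32-bit integer bit patterns --

crc32_table <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit pattern
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(bitwShiftR(c, 1L), poly) else bitwShiftR(c, 1L)
    }
    tab[i + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   crc32_table[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

# -- stored-entry ZIP writer -------------------------------------------------

zip_write_stored <- function(path, entries) {
  stopifnot(is.list(entries), length(names(entries)) == length(entries))
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  offsets <- integer(length(entries))
  crcs <- integer(length(entries))
  pos <- 0L
  for (i in seq_along(entries)) {
    nm <- names(entries)[i]
    data <- entries[[i]]
    crcs[i] <- crc32(data)
    offsets[i] <- pos
    writeBin(as.raw(c(0x50, 0x4b, 0x03, 0x04)), con)
    w2(20); w2(0); w2(0)          # version needed, flags, method=store
    w2(0); w2(0x21)               # mod time, mod date (fixed epoch-ish stamp)
    w4(crcs[i]); w4(length(data)); w4(length(data))
    w2(nchar(nm, type = "bytes")); w2(0)
    writeChar(nm, con, eos = NULL)
    writeBin(data, con)
    pos <- pos + 30L + nchar(nm, type = "bytes") + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    nm <- names(entries)[i]
    data <- entries[[i]]
    writeBin(as.raw(c(0x50, 0x4b, 0x01, 0x02)), con)
    w2(20); w2(20); w2(0); w2(0)  # made-by, needed, flags, method
    w2(0); w2(0x21)
    w4(crcs[i]); w4(length(data)); w4(length(data))
    w2(nchar(nm, type = "bytes")); w2(0); w2(0)
    w2(0); w2(0); w4(0); w4(offsets[i])
    writeChar(nm, con, eos = NULL)
    pos <- pos + 46L + nchar(nm, type = "bytes")
  }
  writeBin(as.raw(c(0x50, 0x4b, 0x05, 0x06)), con)
  w2(0); w2(0); w2(length(entries)); w2(length(entries))
  w4(pos - cd_start); w4(cd_start); w2(0)
  invisible(path)
}
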