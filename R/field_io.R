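# Displacement-field file format: a two-plane (f_x, f_y) baseline TIFF with
# 32-bit IEEE-float samples, one strip per plane, little-endian. Written
# directly with writeBin because the installed raster packages clamp float
# samples to [0, 1] on write, which would destroy displacement values.

FIELD_TIFF_TAGS <- c(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, strip_offsets = 273L, spp = 277L,
  rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L
)

#' Read and write displacement fields
#'
#' Fields are stored as two-plane 32-bit float TIFF files (plane 1 = `f_x`,
#' plane 2 = `f_y`), losslessly. Files with a plane count other than two are
#' rejected.
#'
#' @param field a [displacement_field()].
#' @param path file path (`.tif`/`.tiff`).
#' @return `read_field` returns a [displacement_field()].
#' @export
write_field <- function(field, path) {
  planes <- list(field$f_x, field$f_y)
  h <- nrow(field$f_x); w <- ncol(field$f_x)
  nbytes <- 4L * h * w
  data_off <- c(8L, 8L + nbytes)
  n_entries <- 10L
  ifd_size <- 2L + 12L * n_entries + 4L
  ifd_off <- c(8L + 2L * nbytes, 8L + 2L * nbytes + ifd_size)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(c(42L), con, size = 2, endian = "little")
  writeBin(ifd_off[1], con, size = 4, endian = "little")
  for (p in planes)
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT: left-justified in the 4-byte value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (i in 1:2) {
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(256L, 4L, 1L, w)
    entry(257L, 4L, 1L, h)
    entry(258L, 3L, 1L, 32L)
    entry(259L, 3L, 1L, 1L)
    entry(262L, 3L, 1L, 1L)
    entry(273L, 4L, 1L, data_off[i])
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, h)
    entry(279L, 4L, 1L, nbytes)
    entry(339L, 3L, 1L, 3L)
    writeBin(if (i == 1) ifd_off[2] else 0L, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  if (!file.exists(path)) sil_data_error(sprintf("file not found: %s", path))
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) sil_data_error(sprintf("%s is not a TIFF file", path))
  if (rawToChar(raw[1:2]) != "II")
    sil_data_error("only little-endian ('II') TIFF fields are supported")
  u16 <- function(off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  u32 <- function(off) {
    as.numeric(as.integer(raw[off + 1])) +
      256 * as.integer(raw[off + 2]) +
      65536 * as.integer(raw[off + 3]) +
      16777216 * as.integer(raw[off + 4])
  }
  if (u16(2) != 42L) sil_data_error(sprintf("%s is not a TIFF file", path))

  planes <- list()
  ifd <- u32(4)
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd + 2 + 12 * (k - 1)
      tag <- u16(e); type <- u16(e + 2); count <- u32(e + 4)
      val <- if (type == 3L && count == 1) u16(e + 8) else u32(e + 8)
      tags[[as.character(tag)]] <- list(type = type, count = count, value = val,
                                        value_off = e + 8)
    }
    need <- function(tag) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) sil_data_error(sprintf("field TIFF missing tag %d", tag))
      t
    }
    w <- need(256L)$value; h <- need(257L)$value
    if (need(258L)$value != 32L || (need(339L)$value %||% 0) != 3L)
      sil_data_error("field TIFF must carry 32-bit IEEE-float samples")
    if (need(259L)$value != 1L)
      sil_data_error("compressed field TIFFs are not supported")
    so <- need(273L); sb <- need(279L)
    offsets <- if (so$count == 1) so$value else
      vapply(seq_len(so$count), function(j) u32(so$value + 4 * (j - 1)), 0)
    counts <- if (sb$count == 1) sb$value else
      vapply(seq_len(sb$count), function(j) u32(sb$value + 4 * (j - 1)), 0)
    vals <- unlist(lapply(seq_along(offsets), function(j) {
      readBin(raw[(offsets[j] + 1):(offsets[j] + counts[j])],
              "numeric", n = counts[j] / 4, size = 4, endian = "little")
    }))
    planes[[length(planes) + 1]] <- matrix(vals, h, w, byrow = TRUE)
    ifd <- u32(ifd + 2 + 12 * n)
  }
  if (length(planes) != 2)
    sil_data_error(sprintf(
      "displacement-field TIFF must have exactly 2 planes, found %d",
      length(planes)
    ))
  displacement_field(planes[[1]], planes[[2]])
}
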