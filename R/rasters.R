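#' Slide raster
#'
#' The unit of whole-slide processing: an 8-bit-per-channel RGB raster held
#' as a numeric array in `[0, 1]` with pixel-size metadata. Clinical scans in
#' this workflow are acquired at 40x (0.25 um per pixel), which is the
#' default.
#'
#' @param pixels numeric array `height x width x 3` with values in `[0, 1]`,
#'   or a `height x width` matrix (expanded to grey RGB).
#' @param microns_per_pixel positive scalar; physical pixel pitch.
#' @return an object of class `slide_raster` with elements `pixels` and
#'   `microns_per_pixel`.
#' @export
slide_raster <- function(pixels, microns_per_pixel = 0.25) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    sil_data_error("pixels must be a height x width x 3 array")
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1)
    sil_data_error("slide must be at least 1 x 1")
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0)
    sil_data_error("microns_per_pixel must be > 0")
  structure(
    list(pixels = pixels, microns_per_pixel = microns_per_pixel),
    class = "slide_raster"
  )
}

#' @export
print.slide_raster <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<slide_raster> %d x %d px, %.3g um/px\n", d[1], d[2], x$microns_per_pixel
  ))
  invisible(x)
}

#' @export
dim.slide_raster <- function(x) dim(x$pixels)[1:2]

#' Mask layer
#'
#' A single-channel integer label raster aligned to a slide. Masks are plain
#' integer matrices throughout the package; this constructor validates one
#' against a declared label set.
#'
#' @param values integer matrix (rows = y, columns = x).
#' @param labels named integer vector mapping names to codes; by convention 0
#'   is negative/background and 1 positive/foreground.
#' @return the validated integer matrix, with a `labels` attribute.
#' @export
mask_layer <- function(values, labels = c(background = 0L, positive = 1L)) {
  if (!is.matrix(values)) sil_data_error("mask values must be a matrix")
  storage.mode(values) <- "integer"
  bad <- setdiff(unique(as.vector(values)), unname(labels))
  if (length(bad) > 0)
    sil_data_error(sprintf(
      "mask contains labels outside the declared set: %s",
      paste(bad, collapse = ", ")
    ))
  attr(values, "labels") <- labels
  values
}

as_binary_mask <- function(m) {
  m <- unclass(m)
  if (!is.matrix(m)) sil_data_error("mask must be a matrix")
  storage.mode(m) <- "integer"
  (m != 0L) * 1L
}

#' Read and write rasters
#'
#' PNG and TIFF (8-bit) raster I/O. RGB slides round-trip through
#' [slide_raster()]; masks are read/written as single-channel rasters with
#' integer labels 0..255.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif(f)`).
#' @param microns_per_pixel pixel pitch recorded on the returned slide.
#' @return `read_raster` returns a [slide_raster()]; `read_mask` an integer
#'   matrix.
#' @export
read_raster <- function(path, microns_per_pixel = 0.25) {
  a <- read_any_raster(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  slide_raster(a, microns_per_pixel)
}

#' @rdname read_raster
#' @param slide a [slide_raster()].
#' @export
write_raster <- function(slide, path) {
  write_any_raster(slide$pixels, path)
  invisible(path)
}

#' @rdname read_raster
#' @export
read_mask <- function(path) {
  a <- read_any_raster(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  m <- matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
  m
}

#' @rdname read_raster
#' @param mask integer matrix with values in 0..255.
#' @export
write_mask <- function(mask, path) {
  write_any_raster(matrix(as.numeric(mask) / 255, nrow(mask), ncol(mask)), path)
  invisible(path)
}

read_any_raster <- function(path) {
  if (!file.exists(path)) sil_data_error(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else sil_data_error(sprintf("unsupported raster format: .%s", ext))
}

write_any_raster <- function(a, path) {
  ext <- tolower(tools::file_ext(path))
  a[a < 0] <- 0; a[a > 1] <- 1
  if (ext == "png") png::writePNG(a, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(a, path, bits.per.sample = 8L)
  else sil_data_error(sprintf("unsupported raster format: .%s", ext))
}
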