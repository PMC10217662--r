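#' Tile a slide into fixed windows
#'
#' Cuts a slide into square windows of side `window` pixels (the clinical
#' default is 4096 at 0.25 um/px) and rescales each fragment to the model
#' input side (default equal to `window`, i.e. no rescaling). Windows are
#' half-open `[offset, offset + size)`; the tiles partition the slide exactly,
#' so edge tiles at the right/bottom may be short and carry their own scale
#' factor rather than being padded or dropped.
#'
#' @param x a [slide_raster()] or an integer mask matrix.
#' @param window square window side in pixels.
#' @param model_input side of the emitted tile raster; fragments are rescaled
#'   to `model_input x model_input` (bilinear for RGB, nearest-neighbour for
#'   masks so labels stay integral).
#' @return a list with `grid` (data frame: `row`, `col`, `y`, `x`, `h`, `w` —
#'   0-based offsets and native sizes) and `tiles` (list of rescaled tiles in
#'   grid order).
#' @export
tile_slide <- function(x, window, model_input = window) {
  is_slide <- inherits(x, "slide_raster")
  d <- if (is_slide) dim(x)[1:2] else dim(x)
  if (is.null(d) || d[1] < 1 || d[2] < 1)
    sil_data_error("slide must be at least 1 x 1")
  if (window < 1 || model_input < 1 || window < model_input)
    sil_config_error("need window >= model_input >= 1")

  ys <- seq(0L, d[1] - 1L, by = window)
  xs <- seq(0L, d[2] - 1L, by = window)
  grid <- expand.grid(col = seq_along(xs), row = seq_along(ys))[, 2:1]
  grid$y <- ys[grid$row]
  grid$x <- xs[grid$col]
  grid$h <- pmin(window, d[1] - grid$y)
  grid$w <- pmin(window, d[2] - grid$x)

  tiles <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r <- grid$y[i] + seq_len(grid$h[i])
    c <- grid$x[i] + seq_len(grid$w[i])
    if (is_slide) {
      t_i <- x$pixels[r, c, , drop = FALSE]
      if (model_input != window || grid$h[i] != model_input || grid$w[i] != model_input)
        t_i <- resize_rgb(t_i, model_input, model_input)
    } else {
      t_i <- x[r, c, drop = FALSE]
      if (model_input != window || grid$h[i] != model_input || grid$w[i] != model_input)
        t_i <- resize_nearest(t_i, model_input, model_input)
    }
    tiles[[i]] <- t_i
  }
  list(grid = grid, tiles = tiles)
}

#' Stitch per-tile masks back into a whole-slide mask
#'
#' Inverse of [tile_slide()] for masks: each tile mask is rescaled
#' (nearest-neighbour) to its native window size and placed at its offset.
#' When tiles were produced without rescaling the round trip is bit-exact.
#'
#' @param grid the `grid` data frame from [tile_slide()].
#' @param tile_masks list of integer matrices, one per grid row, each at the
#'   model-input scale (or already at native size).
#' @param slide_shape integer `c(height, width)` of the output mask.
#' @return integer mask matrix of dimension `slide_shape`.
#' @export
stitch_masks <- function(grid, tile_masks, slide_shape) {
  if (length(tile_masks) != nrow(grid))
    sil_data_error("one tile mask per grid entry required")
  out <- matrix(NA_integer_, slide_shape[1], slide_shape[2])
  for (i in seq_len(nrow(grid))) {
    h <- grid$h[i]; w <- grid$w[i]
    if (grid$y[i] + h > slide_shape[1] || grid$x[i] + w > slide_shape[2])
      sil_data_error(sprintf("tile %d exceeds the slide bounds", i))
    m <- tile_masks[[i]]
    storage.mode(m) <- "integer"
    if (nrow(m) != h || ncol(m) != w) m <- resize_nearest(m, h, w)
    r <- grid$y[i] + seq_len(h)
    c <- grid$x[i] + seq_len(w)
    if (any(!is.na(out[r, c])))
      sil_data_error(sprintf("tile %d overlaps a previously placed tile", i))
    out[r, c] <- m
  }
  if (anyNA(out))
    sil_data_error("tiles do not cover the slide: gaps remain after stitching")
  out
}
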